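# Parametric multi-part object templates. Each template names a category,
# carries named default size parameters, and a builder mapping (possibly
# jittered) parameters to a list of primitives plus a primitive -> part map.
# Part ids are contiguous integers starting at 0; every category has 3-12
# parts. y is the vertical (gravity) axis throughout.

#' Define a parametric shape template
#'
#' @param category_name category label.
#' @param defaults named numeric vector of size parameters.
#' @param builder function(params) returning `list(primitives = <list of
#'   primitive>, part_of = <0-based integer part id per primitive>,
#'   part_names = <character>)`.
#' @return A `shape_template`.
#' @export
shape_template <- function(category_name, defaults, builder) {
  stopifnot(is.character(category_name), length(category_name) == 1L,
            is.numeric(defaults), !is.null(names(defaults)),
            is.function(builder))
  tpl <- structure(list(category_name = category_name,
                        defaults = defaults, builder = builder),
                   class = "shape_template")
  built <- builder(as.list(defaults))
  .validate_built(built, category_name)
  tpl
}

.validate_built <- function(built, category_name) {
  if (length(built$primitives) < 1L) {
    stop("template ", category_name, " has no primitives", call. = FALSE)
  }
  po <- as.integer(built$part_of)
  if (length(po) != length(built$primitives)) {
    stop("template ", category_name,
         ": part_of must assign every primitive to exactly one part",
         call. = FALSE)
  }
  ids <- sort(unique(po))
  if (!identical(ids, seq_along(ids) - 1L)) {
    stop("template ", category_name,
         ": part ids must be contiguous integers starting at 0", call. = FALSE)
  }
  np <- length(ids)
  if (np < 3L || np > 12L) {
    stop("template ", category_name, ": part count ", np,
         " outside [3, 12]", call. = FALSE)
  }
  invisible(built)
}

#' @export
print.shape_template <- function(x, ...) {
  b <- x$builder(as.list(x$defaults))
  cat(sprintf("<shape_template> %s: %d primitives, %d parts\n",
              x$category_name, length(b$primitives),
              length(unique(b$part_of))))
  invisible(x)
}

#' Built-in category templates
#'
#' Returns parametric templates for the ten experiment categories (airplane,
#' bottle, bowl, chair, cup, lamp, person, piano, stool, table) plus a car
#' template used by the part-scrambling stimulus pool. Each template has 3-12
#' parts with semantically coherent groupings (e.g. an airplane's wings,
#' body, tail and engines).
#'
#' @param categories optional character vector selecting a subset.
#' @return Named list of `shape_template` objects.
#' @export
shape_templates <- function(categories = NULL) {
  all <- list(
    airplane = .tpl_airplane(), bottle = .tpl_bottle(), bowl = .tpl_bowl(),
    car = .tpl_car(), chair = .tpl_chair(), cup = .tpl_cup(),
    lamp = .tpl_lamp(), person = .tpl_person(), piano = .tpl_piano(),
    stool = .tpl_stool(), table = .tpl_table())
  if (is.null(categories)) return(all)
  missing <- setdiff(categories, names(all))
  if (length(missing)) {
    stop("unknown categories: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  all[categories]
}

#' The ten categories shown in the density/orientation and Lego experiments
#' @return character vector of category names.
#' @export
experiment_categories <- function() {
  c("airplane", "bottle", "bowl", "chair", "cup", "lamp", "person", "piano",
    "stool", "table")
}

#' The five categories used for part scrambling
#' @return character vector of category names.
#' @export
scramble_categories <- function() {
  c("airplane", "car", "chair", "lamp", "table")
}

.tpl_airplane <- function() {
  shape_template("airplane",
    c(body_r = 0.12, body_l = 1.0, wing_span = 1.1, wing_chord = 0.28,
      tail_h = 0.3, engine_r = 0.06),
    function(p) {
      prims <- list(
        primitive("cylinder", center = c(0, 0, 0), axis = "x",
                  r = p$body_r, h = p$body_l / 2, caps = TRUE),
        primitive("cone", center = c(p$body_l / 2, 0, 0), axis = "x",
                  r = p$body_r, h = 0.3 * p$body_l, base = FALSE),
        primitive("box", center = c(0.05, 0, 0),
                  hx = p$wing_chord / 2, hy = 0.02, hz = p$wing_span / 2),
        primitive("box", center = c(-p$body_l / 2 + 0.05, p$tail_h / 2, 0),
                  hx = 0.06, hy = p$tail_h / 2, hz = 0.02),
        primitive("box", center = c(-p$body_l / 2 + 0.05, 0.02, 0),
                  hx = 0.06, hy = 0.02, hz = 0.35 * p$wing_span / 2),
        primitive("cylinder", center = c(0.1, -0.08, 0.3 * p$wing_span),
                  axis = "x", r = p$engine_r, h = 0.12, caps = TRUE),
        primitive("cylinder", center = c(0.1, -0.08, -0.3 * p$wing_span),
                  axis = "x", r = p$engine_r, h = 0.12, caps = TRUE))
      list(primitives = prims, part_of = c(0L, 0L, 1L, 2L, 2L, 3L, 3L),
           part_names = c("body", "wings", "tail", "engines"))
    })
}

.tpl_bottle <- function() {
  shape_template("bottle",
    c(body_r = 0.22, body_h = 0.55, neck_r = 0.07, neck_h = 0.2,
      cap_r = 0.09),
    function(p) {
      prims <- list(
        primitive("cylinder", center = c(0, 0, 0),
                  r = p$body_r, h = p$body_h / 2, caps = TRUE),
        primitive("cylinder", center = c(0, p$body_h / 2 + p$neck_h / 2, 0),
                  r = p$neck_r, h = p$neck_h / 2, caps = FALSE),
        primitive("cylinder", center = c(0, p$body_h / 2 + p$neck_h + 0.03, 0),
                  r = p$cap_r, h = 0.035, caps = TRUE))
      list(primitives = prims, part_of = 0:2,
           part_names = c("body", "neck", "cap"))
    })
}

.tpl_bowl <- function() {
  shape_template("bowl",
    c(shell_r = 0.5, depth = 0.35, rim_r = 0.03, base_r = 0.18),
    function(p) {
      prims <- list(
        primitive("sphere_cap", center = c(0, p$shell_r - p$depth, 0),
                  axis = "ny", r = p$shell_r, h = p$depth),
        primitive("torus_segment",
                  center = c(0, -0.02, 0),
                  R = sqrt(max(p$shell_r^2 - (p$shell_r - p$depth)^2, 1e-4)),
                  r = p$rim_r),
        primitive("cylinder", center = c(0, -p$depth - 0.02, 0),
                  r = p$base_r, h = 0.025, caps = TRUE))
      list(primitives = prims, part_of = 0:2,
           part_names = c("shell", "rim", "base"))
    })
}

.tpl_car <- function() {
  shape_template("car",
    c(body_l = 1.0, body_w = 0.42, body_h = 0.14, cabin_l = 0.45,
      cabin_h = 0.14, wheel_R = 0.09, wheel_r = 0.035),
    function(p) {
      wz <- p$body_w / 2
      wx <- 0.3 * p$body_l
      prims <- list(
        primitive("box", center = c(0, 0, 0),
                  hx = p$body_l / 2, hy = p$body_h, hz = p$body_w / 2),
        primitive("box", center = c(-0.05, p$body_h + p$cabin_h, 0),
                  hx = p$cabin_l / 2, hy = p$cabin_h, hz = 0.8 * p$body_w / 2),
        primitive("torus_segment", center = c(wx, -p$body_h, wz), axis = "z",
                  R = p$wheel_R, r = p$wheel_r),
        primitive("torus_segment", center = c(wx, -p$body_h, -wz), axis = "z",
                  R = p$wheel_R, r = p$wheel_r),
        primitive("torus_segment", center = c(-wx, -p$body_h, wz), axis = "z",
                  R = p$wheel_R, r = p$wheel_r),
        primitive("torus_segment", center = c(-wx, -p$body_h, -wz), axis = "z",
                  R = p$wheel_R, r = p$wheel_r))
      list(primitives = prims, part_of = c(0L, 1L, 2L, 2L, 2L, 2L),
           part_names = c("body", "cabin", "wheels"))
    })
}

.tpl_chair <- function() {
  shape_template("chair",
    c(seat_w = 0.5, seat_d = 0.5, seat_t = 0.04, back_h = 0.55,
      leg_h = 0.45, leg_t = 0.03),
    function(p) {
      lx <- p$seat_d / 2 - p$leg_t
      lz <- p$seat_w / 2 - p$leg_t
      leg <- function(x, z) {
        primitive("box", center = c(x, -p$leg_h / 2, z),
                  hx = p$leg_t, hy = p$leg_h / 2, hz = p$leg_t)
      }
      prims <- list(
        primitive("box", center = c(0, 0, 0),
                  hx = p$seat_d / 2, hy = p$seat_t, hz = p$seat_w / 2),
        primitive("box", center = c(-p$seat_d / 2 + 0.02, p$back_h / 2, 0),
                  hx = 0.02, hy = p$back_h / 2, hz = p$seat_w / 2),
        leg(lx, lz), leg(lx, -lz), leg(-lx, lz), leg(-lx, -lz))
      list(primitives = prims, part_of = c(0L, 1L, 2L, 2L, 2L, 2L),
           part_names = c("seat", "back", "legs"))
    })
}

.tpl_cup <- function() {
  shape_template("cup",
    c(body_r = 0.3, body_h = 0.4, handle_R = 0.16, handle_r = 0.035,
      rim_r = 0.02),
    function(p) {
      prims <- list(
        primitive("cylinder", center = c(0, 0, 0),
                  r = p$body_r, h = p$body_h / 2, caps = TRUE),
        primitive("torus_segment", center = c(p$body_r + 0.4 * p$handle_R, 0, 0),
                  axis = "z", R = p$handle_R, r = p$handle_r,
                  a0 = -pi / 2, a1 = pi / 2),
        primitive("torus_segment", center = c(0, p$body_h / 2, 0),
                  R = p$body_r, r = p$rim_r))
      list(primitives = prims, part_of = 0:2,
           part_names = c("body", "handle", "rim"))
    })
}

.tpl_lamp <- function() {
  shape_template("lamp",
    c(base_r = 0.25, base_h = 0.03, pole_r = 0.03, pole_h = 0.8,
      shade_r = 0.3, shade_h = 0.3),
    function(p) {
      prims <- list(
        primitive("cylinder", center = c(0, -p$pole_h / 2, 0),
                  r = p$base_r, h = p$base_h, caps = TRUE),
        primitive("cylinder", center = c(0, 0, 0),
                  r = p$pole_r, h = p$pole_h / 2, caps = FALSE),
        primitive("cone", center = c(0, p$pole_h / 2, 0),
                  r = p$shade_r, h = p$shade_h, base = FALSE))
      list(primitives = prims, part_of = 0:2,
           part_names = c("base", "pole", "shade"))
    })
}

.tpl_person <- function() {
  shape_template("person",
    c(head_r = 0.12, torso_w = 0.34, torso_h = 0.5, limb_r = 0.05,
      arm_l = 0.42, leg_l = 0.55),
    function(p) {
      prims <- list(
        primitive("sphere_cap", center = c(0, p$torso_h / 2 + p$head_r + 0.02, 0),
                  r = p$head_r, h = 2 * p$head_r),
        primitive("box", center = c(0, 0, 0),
                  hx = 0.1, hy = p$torso_h / 2, hz = p$torso_w / 2),
        primitive("cylinder",
                  center = c(0, p$torso_h / 2 - p$arm_l / 2,
                             p$torso_w / 2 + p$limb_r),
                  r = p$limb_r, h = p$arm_l / 2, caps = TRUE),
        primitive("cylinder",
                  center = c(0, p$torso_h / 2 - p$arm_l / 2,
                             -p$torso_w / 2 - p$limb_r),
                  r = p$limb_r, h = p$arm_l / 2, caps = TRUE),
        primitive("cylinder",
                  center = c(0, -p$torso_h / 2 - p$leg_l / 2, p$torso_w / 4),
                  r = p$limb_r, h = p$leg_l / 2, caps = TRUE),
        primitive("cylinder",
                  center = c(0, -p$torso_h / 2 - p$leg_l / 2, -p$torso_w / 4),
                  r = p$limb_r, h = p$leg_l / 2, caps = TRUE))
      list(primitives = prims, part_of = c(0L, 1L, 2L, 2L, 3L, 3L),
           part_names = c("head", "torso", "arms", "legs"))
    })
}

.tpl_piano <- function() {
  shape_template("piano",
    c(body_w = 1.0, body_d = 0.5, body_h = 0.5, key_d = 0.18,
      leg_h = 0.35, leg_t = 0.04),
    function(p) {
      lx <- p$body_d / 2 - p$leg_t
      lz <- p$body_w / 2 - p$leg_t
      leg <- function(x, z) {
        primitive("box", center = c(x, -p$leg_h / 2, z),
                  hx = p$leg_t, hy = p$leg_h / 2, hz = p$leg_t)
      }
      prims <- list(
        primitive("box", center = c(0, p$body_h / 2, 0),
                  hx = p$body_d / 2, hy = p$body_h / 2, hz = p$body_w / 2),
        primitive("box", center = c(p$body_d / 2 + p$key_d / 2, 0.12, 0),
                  hx = p$key_d / 2, hy = 0.03, hz = 0.85 * p$body_w / 2),
        leg(lx, lz), leg(lx, -lz), leg(-lx, lz), leg(-lx, -lz),
        primitive("box", center = c(0, p$body_h + 0.02, 0),
                  hx = p$body_d / 2, hy = 0.015, hz = p$body_w / 2))
      list(primitives = prims, part_of = c(0L, 1L, 2L, 2L, 2L, 2L, 3L),
           part_names = c("body", "keyboard", "legs", "lid"))
    })
}

.tpl_stool <- function() {
  shape_template("stool",
    c(seat_r = 0.25, seat_t = 0.035, leg_r = 0.03, leg_h = 0.55,
      ring_R = 0.2, ring_r = 0.02),
    function(p) {
      leg <- function(ang) {
        primitive("cylinder",
                  center = c(0.8 * p$seat_r * cos(ang), -p$leg_h / 2,
                             0.8 * p$seat_r * sin(ang)),
                  r = p$leg_r, h = p$leg_h / 2, caps = FALSE)
      }
      prims <- list(
        primitive("cylinder", center = c(0, 0, 0),
                  r = p$seat_r, h = p$seat_t, caps = TRUE),
        leg(0), leg(2 * pi / 3), leg(4 * pi / 3),
        primitive("torus_segment", center = c(0, -0.6 * p$leg_h, 0),
                  R = p$ring_R, r = p$ring_r))
      list(primitives = prims, part_of = c(0L, 1L, 1L, 1L, 2L),
           part_names = c("seat", "legs", "footrest"))
    })
}

.tpl_table <- function() {
  shape_template("table",
    c(top_w = 1.0, top_d = 0.6, top_t = 0.035, leg_h = 0.5, leg_t = 0.035),
    function(p) {
      lx <- p$top_d / 2 - 2 * p$leg_t
      lz <- p$top_w / 2 - 2 * p$leg_t
      leg <- function(x, z) {
        primitive("box", center = c(x, -p$leg_h / 2, z),
                  hx = p$leg_t, hy = p$leg_h / 2, hz = p$leg_t)
      }
      prims <- list(
        primitive("box", center = c(0, 0, 0),
                  hx = p$top_d / 2, hy = p$top_t, hz = p$top_w / 2),
        leg(lx, lz), leg(lx, -lz), leg(-lx, lz), leg(-lx, -lz),
        primitive("box", center = c(0, -2.5 * p$top_t, 0),
                  hx = p$top_d / 2 - p$leg_t, hy = p$top_t / 2,
                  hz = p$top_w / 2 - p$leg_t))
      list(primitives = prims, part_of = c(0L, 1L, 1L, 1L, 1L, 2L),
           part_names = c("top", "legs", "apron"))
    })
}
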