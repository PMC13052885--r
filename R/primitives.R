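# Geometric primitives with analytic surface areas and area-uniform surface
# samplers. Each primitive is defined in a canonical frame with y as its axis,
# then mapped by an axis permutation and a translation. Templates are built
# from these; area weighting across primitives gives uniform sampling over the
# union of surfaces.

# axis permutation: rotates the canonical y axis onto the requested axis
.axis_map <- function(axis) {
  switch(axis,
    y = diag(3),
    x = matrix(c(0, 1, 0, 1, 0, 0, 0, 0, 1), 3, 3), # swap x/y
    z = matrix(c(1, 0, 0, 0, 0, 1, 0, 1, 0), 3, 3), # swap y/z
    ny = diag(c(1, -1, -1)), # y axis flipped (180 deg rotation about x)
    stop("unknown axis: ", axis, call. = FALSE)
  )
}

#' Create a surface primitive
#'
#' Supported kinds: `box` (half-sizes hx, hy, hz), `cylinder` (radius r,
#' half-height h, optional end caps), `cone` (base radius r, height h,
#' optional base disc), `sphere_cap` (sphere radius r, band height h
#' starting h0 below the top pole, default h0 = 0; h = 2r gives the full
#' sphere), and `torus_segment`
#' (major radius R, minor radius r, major-angle range). `axis` orients the
#' canonical vertical axis; `center` translates the primitive.
#'
#' @param kind primitive kind.
#' @param center length-3 translation.
#' @param axis one of "x", "y", "z".
#' @param ... size parameters, see Details.
#' @return A `primitive` object with an analytic `area`.
#' @export
primitive <- function(kind = c("box", "cylinder", "cone", "sphere_cap",
                               "torus_segment"),
                      center = c(0, 0, 0), axis = "y", ...) {
  kind <- match.arg(kind)
  p <- list(kind = kind, center = as.numeric(center), axis = axis,
            pars = list(...))
  p$area <- .prim_area(p)
  if (!is.finite(p$area) || p$area < 0) {
    stop("invalid primitive sizes for kind ", kind, call. = FALSE)
  }
  structure(p, class = "primitive")
}

.prim_area <- function(p) {
  q <- p$pars
  switch(p$kind,
    box = {
      8 * (q$hx * q$hy + q$hy * q$hz + q$hx * q$hz)
    },
    cylinder = {
      caps <- isTRUE(q$caps)
      2 * pi * q$r * (2 * q$h) + if (caps) 2 * pi * q$r^2 else 0
    },
    cone = {
      base <- isTRUE(q$base)
      pi * q$r * sqrt(q$r^2 + q$h^2) + if (base) pi * q$r^2 else 0
    },
    sphere_cap = 2 * pi * q$r * q$h, # independent of the band offset h0
    torus_segment = {
      a0 <- if (is.null(q$a0)) 0 else q$a0
      a1 <- if (is.null(q$a1)) 2 * pi else q$a1
      (a1 - a0) * 2 * pi * q$R * q$r
    }
  )
}

# sample n points area-uniformly on the primitive surface (canonical frame),
# then map into world coordinates
.prim_sample <- function(p, n) {
  if (n == 0L) return(matrix(numeric(0), 0, 3))
  q <- p$pars
  pts <- switch(p$kind,
    box = {
      hx <- q$hx; hy <- q$hy; hz <- q$hz
      areas <- c(hy * hz, hy * hz, hx * hz, hx * hz, hx * hy, hx * hy) * 4
      face <- sample.int(6, n, replace = TRUE, prob = areas)
      u <- runif(n, -1, 1); v <- runif(n, -1, 1)
      out <- matrix(0, n, 3)
      for (f in 1:6) {
        i <- which(face == f)
        if (!length(i)) next
        out[i, ] <- switch(f,
          cbind( hx, u[i] * hy, v[i] * hz),
          cbind(-hx, u[i] * hy, v[i] * hz),
          cbind(u[i] * hx,  hy, v[i] * hz),
          cbind(u[i] * hx, -hy, v[i] * hz),
          cbind(u[i] * hx, v[i] * hy,  hz),
          cbind(u[i] * hx, v[i] * hy, -hz))
      }
      out
    },
    cylinder = {
      lat <- 2 * pi * q$r * (2 * q$h)
      cap <- if (isTRUE(q$caps)) pi * q$r^2 else 0
      which_part <- sample.int(3, n, replace = TRUE, prob = c(lat, cap, cap))
      th <- runif(n, 0, 2 * pi)
      out <- matrix(0, n, 3)
      i <- which(which_part == 1L)
      out[i, ] <- cbind(q$r * cos(th[i]), runif(length(i), -q$h, q$h),
                        q$r * sin(th[i]))
      for (s in c(2L, 3L)) {
        i <- which(which_part == s)
        if (!length(i)) next
        rr <- q$r * sqrt(runif(length(i)))
        out[i, ] <- cbind(rr * cos(th[i]), if (s == 2L) q$h else -q$h,
                          rr * sin(th[i]))
      }
      out
    },
    cone = {
      # apex at y = h, base disc at y = 0
      lat <- pi * q$r * sqrt(q$r^2 + q$h^2)
      base <- if (isTRUE(q$base)) pi * q$r^2 else 0
      which_part <- sample.int(2, n, replace = TRUE, prob = c(lat, base))
      th <- runif(n, 0, 2 * pi)
      out <- matrix(0, n, 3)
      i <- which(which_part == 1L)
      if (length(i)) {
        rr <- q$r * sqrt(runif(length(i))) # radius density ~ r on the slant
        out[i, ] <- cbind(rr * cos(th[i]), q$h * (1 - rr / q$r), rr * sin(th[i]))
      }
      i <- which(which_part == 2L)
      if (length(i)) {
        rr <- q$r * sqrt(runif(length(i)))
        out[i, ] <- cbind(rr * cos(th[i]), 0, rr * sin(th[i]))
      }
      out
    },
    sphere_cap = {
      # area element on a sphere is uniform in y: sample a band of height h
      # starting h0 below the top pole (h0 = 0: a polar cap)
      h0 <- if (is.null(q$h0)) 0 else q$h0
      y <- runif(n, q$r - h0 - q$h, q$r - h0)
      th <- runif(n, 0, 2 * pi)
      rho <- sqrt(pmax(q$r^2 - y^2, 0))
      cbind(rho * cos(th), y, rho * sin(th))
    },
    torus_segment = {
      a0 <- if (is.null(q$a0)) 0 else q$a0
      a1 <- if (is.null(q$a1)) 2 * pi else q$a1
      u <- runif(n, a0, a1)
      # minor angle density proportional to (R + r cos v): rejection sample
      v <- numeric(n); got <- 0L
      while (got < n) {
        m <- (n - got) * 2L + 8L
        cand <- runif(m, 0, 2 * pi)
        keep <- runif(m) < (q$R + q$r * cos(cand)) / (q$R + q$r)
        cand <- cand[keep]
        take <- min(length(cand), n - got)
        if (take > 0) {
          v[(got + 1L):(got + take)] <- cand[seq_len(take)]
          got <- got + take
        }
      }
      cx <- (q$R + q$r * cos(v))
      cbind(cx * cos(u), q$r * sin(v), cx * sin(u))
    }
  )
  rot <- .axis_map(p$axis)
  sweep(pts %*% rot, 2, p$center, "+")
}
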