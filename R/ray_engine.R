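# Non-sequential propagation engine. Each iteration finds, for every live
# ray, the nearest forward object, then applies that object's interaction:
# Snell refraction with deterministic Fresnel splitting, absorption, ideal
# mirror reflection, anti-reflecting transmission, or diffuse (Lambertian /
# isotropic) edge scattering. Energy is audited in a ledger that must close
# to 1e-9 relative on every run.

#' Vector Snell refraction
#'
#' @param direction Unit 3-vector (or n x 3 matrix) of incident directions.
#' @param normal Unit 3-vector (or n x 3 matrix) of surface normals; either
#'   orientation is accepted.
#' @param n1,n2 Refractive indices of the incident and transmitting media.
#' @return A list with `dir` (transmitted unit direction(s); rows are `NA`
#'   under total internal reflection) and `tir` (logical vector).
#' @examples
#' refract(c(0, 0, 1), c(0, 0, 1), 1, 1.5)      # normal incidence
#' @export
refract <- function(direction, normal, n1, n2) {
  D <- if (is.matrix(direction)) direction else matrix(direction, ncol = 3)
  N <- if (is.matrix(normal)) normal else matrix(normal, ncol = 3)
  if (nrow(N) == 1L && nrow(D) > 1L) N <- N[rep(1L, nrow(D)), , drop = FALSE]
  dn <- rowSums(D * N)
  Ni <- N * ifelse(dn > 0, -1, 1)        # oriented against the ray
  cosi <- pmin(1, -rowSums(D * Ni))
  eta <- n1 / n2
  sin2t <- eta^2 * (1 - cosi^2)
  tir <- sin2t > 1
  cost <- sqrt(pmax(0, 1 - sin2t))
  Td <- eta * D + (eta * cosi - cost) * Ni
  Td <- Td / sqrt(rowSums(Td^2))
  Td[tir, ] <- NA_real_
  list(dir = if (is.matrix(direction)) Td else Td[1, ], tir = tir)
}

#' Unpolarized Fresnel reflectance
#'
#' Average of the s- and p-polarized power reflectances for a smooth
#' dielectric interface; returns 1 under total internal reflection.
#'
#' @param theta Angle of incidence in radians (vectorized), in `[0, pi/2]`.
#' @param n1,n2 Refractive indices of the incident and transmitting media.
#' @return Reflectance in `[0, 1]`.
#' @examples
#' fresnel_unpolarized(0, 1, 1.5)   # 0.04
#' @export
fresnel_unpolarized <- function(theta, n1, n2) {
  stopifnot(all(theta >= 0 & theta <= pi / 2 + 1e-12), n1 > 0, n2 > 0)
  cosi <- cos(theta)
  sin2t <- (n1 / n2)^2 * (1 - cosi^2)
  tir <- sin2t > 1
  cost <- sqrt(pmax(0, 1 - sin2t))
  .fresnel_R(cosi, cost, n1, n2, tir)
}

.fresnel_R <- function(cosi, cost, n1, n2, tir) {
  rs <- ((n1 * cosi - n2 * cost) / (n1 * cosi + n2 * cost))^2
  rp <- ((n1 * cost - n2 * cosi) / (n1 * cost + n2 * cosi))^2
  R <- (rs + rp) / 2
  R[tir] <- 1
  R
}

#' Diffuse hemisphere direction sampling
#'
#' Samples scatter directions in the hemisphere about `normal`, either
#' cosine-weighted (`"lambertian"`, radiance independent of view angle) or
#' uniform in solid angle (`"isotropic"`). Uses the current R RNG stream;
#' seed externally for reproducibility.
#'
#' @param n Number of directions.
#' @param normal Unit 3-vector: hemisphere axis.
#' @param model `"lambertian"` (default) or `"isotropic"`.
#' @return An n x 3 matrix of unit directions, all with positive dot product
#'   with `normal`.
#' @export
scatter_hemisphere <- function(n, normal = c(0, 0, 1),
                               model = c("lambertian", "isotropic")) {
  model <- match.arg(model)
  u1 <- stats::runif(n)
  u2 <- stats::runif(n)
  if (model == "lambertian") {
    ct <- sqrt(u1)            # cos(theta) ~ sqrt(U): pdf 2 cos(theta) sin(theta)
  } else {
    ct <- u1                  # uniform in solid angle on the hemisphere
  }
  st <- sqrt(pmax(0, 1 - ct^2))
  phi <- 2 * pi * u2
  local <- cbind(st * cos(phi), st * sin(phi), ct)
  # rotate local +z onto the requested axis
  a <- normal / sqrt(sum(normal^2))
  helper <- if (abs(a[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  e1 <- c(a[2] * helper[3] - a[3] * helper[2],
          a[3] * helper[1] - a[1] * helper[3],
          a[1] * helper[2] - a[2] * helper[1])
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(a[2] * e1[3] - a[3] * e1[2],
          a[3] * e1[1] - a[1] * e1[3],
          a[1] * e1[2] - a[2] * e1[1])
  local[, 1, drop = FALSE] %*% rbind(e1) +
    local[, 2, drop = FALSE] %*% rbind(e2) +
    local[, 3, drop = FALSE] %*% rbind(a)
}

# Vectorized hemisphere sampling about per-row axes: returns an (m*K) x 3
# matrix, K consecutive rows per input axis row.
.scatter_rows <- function(axes, K, model) {
  m <- nrow(axes)
  n <- m * K
  u1 <- stats::runif(n)
  u2 <- stats::runif(n)
  ct <- if (model == "lambertian") sqrt(u1) else u1
  st <- sqrt(pmax(0, 1 - ct^2))
  phi <- 2 * pi * u2
  lx <- st * cos(phi); ly <- st * sin(phi)
  A <- axes[rep(seq_len(m), each = K), , drop = FALSE]
  # per-row orthonormal frame (helper chosen away from the axis)
  use_z <- abs(A[, 3]) < 0.9
  H <- cbind(ifelse(use_z, 0, 1), 0, ifelse(use_z, 1, 0))
  E1 <- cbind(A[, 2] * H[, 3] - A[, 3] * H[, 2],
              A[, 3] * H[, 1] - A[, 1] * H[, 3],
              A[, 1] * H[, 2] - A[, 2] * H[, 1])
  E1 <- E1 / sqrt(rowSums(E1^2))
  E2 <- cbind(A[, 2] * E1[, 3] - A[, 3] * E1[, 2],
              A[, 3] * E1[, 1] - A[, 1] * E1[, 3],
              A[, 1] * E1[, 2] - A[, 2] * E1[, 1])
  lx * E1 + ly * E2 + ct * A
}

#' Trace policy: splitting and termination controls
#'
#' @param energy_cutoff Child rays below this fraction of the mean initial
#'   per-ray energy are terminated (booked as cutoff). Default 1e-4.
#' @param max_generation Maximum split depth; deeper children are cut off.
#' @param max_events Hard cap on interactions per ray (guards against
#'   pathological bounce loops).
#' @param scatter_children Number of scattered child rays spawned per
#'   Fresnel portion at a frosted edge.
#' @param scatter_model `"lambertian"` or `"isotropic"` hemisphere sampling
#'   for the frosted edge.
#' @param seed Integer seed for the scatter RNG (the only stochastic step).
#' @return A list of class `trace_policy`.
#' @export
trace_policy <- function(energy_cutoff = 1e-4, max_generation = 8L,
                         max_events = 64L, scatter_children = 8L,
                         scatter_model = c("lambertian", "isotropic"),
                         seed = 1L) {
  scatter_model <- match.arg(scatter_model)
  structure(list(energy_cutoff = energy_cutoff,
                 max_generation = as.integer(max_generation),
                 max_events = as.integer(max_events),
                 scatter_children = as.integer(scatter_children),
                 scatter_model = scatter_model,
                 seed = as.integer(seed)),
            class = "trace_policy")
}

# interaction-path class of a terminated ray, from its tag counters.
# Precedence: any edge reflection > edge transmission > interspace
# (passed the pupil, never touched optic or edge) > direct > other.
.classify <- function(iris, optic, edgeT, edgeR) {
  cls <- rep("other", length(iris))
  cls[iris > 0 & optic > 0] <- "direct"
  cls[iris > 0 & optic == 0 & edgeT == 0 & edgeR == 0] <- "interspace"
  cls[edgeT > 0] <- "edge_transmitted"
  cls[edgeR > 0] <- "edge_reflected"
  cls
}

#' Tag classes used for retinal attribution
#' @export
tag_classes <- c("direct", "interspace", "edge_transmitted",
                 "edge_reflected", "other")

# dispatch: travel distance of every ray to one object (Inf = miss)
.object_t <- function(obj, P, D) {
  switch(obj$kind,
    asphere    = intersect_asphere(obj$profile, obj$z0, P, D),
    plane      = {
      t <- ifelse(abs(D[, 3]) > 1e-300, (obj$z0 - P[, 3]) / D[, 3], Inf)
      x <- P[, 1] + t * D[, 1]
      y <- P[, 2] + t * D[, 2]
      r <- sqrt(x^2 + y^2)
      ifelse(t > .GEOM_EPS & r <= obj$outer_radius, t, Inf)
    },
    cylinder   = intersect_cylinder(obj$radius, obj$z1, obj$z2, P, D),
    halfsphere = intersect_halfsphere(obj$center_z, obj$radius, P, D))
}

# unit normal of one object at hit points X (n x 3), with a fixed geometric
# orientation: +z-ish for sag sheets and planes, radially outward for the
# edge cylinder, outward (away from the retina centre) for the retina.
.object_normal <- function(obj, X) {
  n <- nrow(X)
  switch(obj$kind,
    asphere = {
      rel <- cbind(X[, 1], X[, 2], X[, 3] - obj$z0)
      surface_normal(obj$profile, rel)
    },
    plane = matrix(rep(c(0, 0, 1), each = n), n, 3),
    cylinder = {
      r <- sqrt(X[, 1]^2 + X[, 2]^2)
      cbind(X[, 1] / r, X[, 2] / r, 0)
    },
    halfsphere = {
      rel <- cbind(X[, 1], X[, 2], X[, 3] - obj$center_z)
      rel / sqrt(rowSums(rel^2))
    })
}

#' Trace a ray bundle through the eye model
#'
#' Runs the non-sequential loop to completion: every ray is followed (with
#' its Fresnel-split descendants) until it reaches the retina, is absorbed,
#' escapes the model, or is terminated by the energy/generation cutoffs.
#'
#' @param model An [build_model()] result.
#' @param bundle A ray bundle from [make_bundle()] or [visual_axis_bundle()]:
#'   a list with `P` (n x 3 origins), `D` (n x 3 unit directions), `E`
#'   (energies).
#' @param policy A [trace_policy()].
#' @return A list of class `trace_result`:
#'   \describe{
#'     \item{hits}{data.frame of retinal hits: `x,y,z` (mm), `dx,dy,dz`
#'       (arrival direction), `energy`, `class` (see [tag_classes]).}
#'     \item{ledger}{named energy audit: emitted, retina, absorbed (by
#'       object), escaped, cutoff; closes to 1e-9 relative.}
#'     \item{n_events}{total interaction count.}
#'     \item{newton_failures}{count of non-converged intersections (treated
#'       as misses).}
#'   }
#' @export
trace <- function(model, bundle, policy = trace_policy()) {
  stopifnot(inherits(model, "eye_model"))
  objs <- model$objects
  nobj <- length(objs)
  set.seed(policy$seed)

  P <- bundle$P; D <- bundle$D; E <- bundle$E
  n0 <- length(E)
  emitted <- sum(E)
  cut <- policy$energy_cutoff * emitted / n0

  gen  <- integer(n0)
  nev  <- integer(n0)
  tIris <- integer(n0); tOpt <- integer(n0)
  tEdgeT <- integer(n0); tEdgeR <- integer(n0)

  led <- c(retina = 0, escaped = 0, cutoff = 0)
  absorbed <- stats::setNames(numeric(nobj), vapply(objs, `[[`, "", "name"))
  nonconv <- 0L
  n_events <- 0L

  hit_acc <- list()

  while (length(E) > 0) {
    n <- length(E)
    tbest <- rep(Inf, n)
    hit <- integer(n)
    for (j in seq_len(nobj)) {
      tj <- .object_t(objs[[j]], P, D)
      nc <- attr(tj, "nonconv")
      if (!is.null(nc)) nonconv <- nonconv + nc
      better <- tj < tbest
      tbest[better] <- tj[better]
      hit[better] <- j
    }

    esc <- hit == 0L
    if (any(esc)) led["escaped"] <- led["escaped"] + sum(E[esc])

    # accumulators for the next iteration
    nxt <- list(P = list(), D = list(), E = list(), gen = list(),
                nev = list(), tIris = list(), tOpt = list(),
                tEdgeT = list(), tEdgeR = list())
    push <- function(P., D., E., gen., nev., i., o., et., er.) {
      k <- length(nxt$P) + 1L
      nxt$P[[k]] <<- P.; nxt$D[[k]] <<- D.; nxt$E[[k]] <<- E.
      nxt$gen[[k]] <<- gen.; nxt$nev[[k]] <<- nev.
      nxt$tIris[[k]] <<- i.; nxt$tOpt[[k]] <<- o.
      nxt$tEdgeT[[k]] <<- et.; nxt$tEdgeR[[k]] <<- er.
    }
    # children filtered by the termination policy before being pushed
    submit <- function(P., D., E., gen., nev., i., o., et., er.) {
      dead <- E. < cut | gen. > policy$max_generation |
        nev. > policy$max_events
      if (any(dead)) led["cutoff"] <<- led["cutoff"] + sum(E.[dead])
      if (any(!dead))
        push(P.[!dead, , drop = FALSE], D.[!dead, , drop = FALSE],
             E.[!dead], gen.[!dead], nev.[!dead], i.[!dead], o.[!dead],
             et.[!dead], er.[!dead])
    }

    for (j in sort(unique(hit[hit > 0L]))) {
      idx <- which(hit == j)
      obj <- objs[[j]]
      X <- P[idx, , drop = FALSE] + tbest[idx] * D[idx, , drop = FALSE]
      Dj <- D[idx, , drop = FALSE]
      Ej <- E[idx]
      gj <- gen[idx]; vj <- nev[idx] + 1L
      ii <- tIris[idx]; oo <- tOpt[idx]
      et <- tEdgeT[idx]; er <- tEdgeR[idx]
      n_events <- n_events + length(idx)

      beh <- obj$behavior
      if (beh == "detector") {
        led["retina"] <- led["retina"] + sum(Ej)
        hit_acc[[length(hit_acc) + 1L]] <- data.frame(
          x = X[, 1], y = X[, 2], z = X[, 3],
          dx = Dj[, 1], dy = Dj[, 2], dz = Dj[, 3],
          energy = Ej, class = .classify(ii, oo, et, er),
          n_iris = ii, n_optic = oo, n_edge_t = et, n_edge_r = er,
          generation = gj)
        next
      }
      if (beh == "absorb") {
        absorbed[j] <- absorbed[j] + sum(Ej)
        next
      }
      if (beh == "iris") {
        rel <- sqrt((X[, 1] - obj$hole_center[1])^2 +
                    (X[, 2] - obj$hole_center[2])^2)
        through <- rel <= obj$hole_radius
        if (any(!through))
          absorbed[j] <- absorbed[j] + sum(Ej[!through])
        if (any(through)) {
          s <- which(through)
          submit(X[s, , drop = FALSE], Dj[s, , drop = FALSE], Ej[s],
                 gj[s], vj[s], ii[s] + 1L, oo[s], et[s], er[s])
        }
        next
      }

      # interface physics: need normals, incident side, Fresnel terms
      N <- .object_normal(obj, X)
      dn <- rowSums(Dj * N)
      Ni <- N * ifelse(dn > 0, -1, 1)
      cosi <- pmin(1, -rowSums(Dj * Ni))
      if (obj$kind == "cylinder") {
        from_in <- dn > 0                 # moving outward: incident from IOL
        n1 <- ifelse(from_in, obj$n_in, obj$n_out)
        n2 <- ifelse(from_in, obj$n_out, obj$n_in)
      } else {
        to_pos <- dn > 0                  # crossing toward the +z side
        n1 <- ifelse(to_pos, obj$n_neg, obj$n_pos)
        n2 <- ifelse(to_pos, obj$n_pos, obj$n_neg)
      }
      eta <- n1 / n2
      sin2t <- eta^2 * (1 - cosi^2)
      tir <- sin2t > 1
      cost <- sqrt(pmax(0, 1 - sin2t))
      Rf <- .fresnel_R(cosi, cost, n1, n2, tir)
      Td <- eta * Dj + (eta * cosi - cost) * Ni
      Td <- Td / sqrt(rowSums(Td^2))
      Rd <- Dj + 2 * cosi * Ni

      is_edge <- identical(obj$tag, "edge")
      oo2 <- if (identical(obj$tag, "optic")) oo + 1L else oo

      if (beh == "mirror") {
        submit(X, Rd, Ej, gj, vj, ii, oo2, et,
               if (is_edge) er + 1L else er)
        next
      }
      if (beh == "anti_reflect") {
        # pure transmission; TIR has no transmitted solution -> absorbed
        if (any(tir)) absorbed[j] <- absorbed[j] + sum(Ej[tir])
        s <- which(!tir)
        if (length(s))
          submit(X[s, , drop = FALSE], Td[s, , drop = FALSE], Ej[s],
                 gj[s], vj[s], ii[s], oo2[s],
                 if (is_edge) et[s] + 1L else et[s], er[s])
        next
      }
      if (beh == "scatter") {
        # frosted edge: both Fresnel portions are diffused
        K <- policy$scatter_children
        for (side in c("T", "R")) {
          Eside <- if (side == "T") Ej * (1 - Rf) else Ej * Rf
          axis_sign <- if (side == "T") -1 else 1
          live <- which(Eside > 0)
          if (!length(live)) next
          rep_idx <- rep(live, each = K)
          dirs <- .scatter_rows(axis_sign * Ni[live, , drop = FALSE], K,
                                policy$scatter_model)
          submit(X[rep_idx, , drop = FALSE], dirs, Eside[rep_idx] / K,
                 gj[rep_idx] + 1L, vj[rep_idx], ii[rep_idx], oo2[rep_idx],
                 if (side == "T") et[rep_idx] + 1L else et[rep_idx],
                 if (side == "R") er[rep_idx] + 1L else er[rep_idx])
        }
        next
      }

      # standard dielectric: deterministic Fresnel split
      Etr <- Ej * (1 - Rf)
      Erf <- Ej * Rf
      s <- which(!tir & Etr > 0)
      if (length(s))
        submit(X[s, , drop = FALSE], Td[s, , drop = FALSE], Etr[s],
               gj[s], vj[s], ii[s], oo2[s],
               if (is_edge) et[s] + 1L else et[s], er[s])
      if (any(Erf > 0))
        submit(X, Rd, Erf, gj + 1L, vj, ii, oo2, et,
               if (is_edge) er + 1L else er)
    }

    if (length(nxt$P)) {
      P <- do.call(rbind, nxt$P)
      D <- do.call(rbind, nxt$D)
      E <- do.call(c, nxt$E)
      gen <- do.call(c, nxt$gen)
      nev <- do.call(c, nxt$nev)
      tIris <- do.call(c, nxt$tIris)
      tOpt <- do.call(c, nxt$tOpt)
      tEdgeT <- do.call(c, nxt$tEdgeT)
      tEdgeR <- do.call(c, nxt$tEdgeR)
    } else {
      E <- numeric(0)
    }
  }

  hits <- if (length(hit_acc)) do.call(rbind, hit_acc) else
    data.frame(x = numeric(0), y = numeric(0), z = numeric(0),
               dx = numeric(0), dy = numeric(0), dz = numeric(0),
               energy = numeric(0), class = character(0))

  total <- led[["retina"]] + led[["escaped"]] + led[["cutoff"]] +
    sum(absorbed)
  if (abs(total - emitted) > 1e-9 * emitted)
    stop(sprintf("energy ledger imbalance: emitted %.12g, accounted %.12g",
                 emitted, total))

  structure(list(hits = hits,
                 ledger = list(emitted = emitted, retina = led[["retina"]],
                               absorbed = absorbed,
                               escaped = led[["escaped"]],
                               cutoff = led[["cutoff"]]),
                 n_events = n_events,
                 newton_failures = nonconv,
                 policy = policy),
            class = "trace_result")
}

#' @export
print.trace_result <- function(x, ...) {
  l <- x$ledger
  cat("Non-sequential trace result\n")
  cat(sprintf("  emitted  %.6f\n  retina   %.6f\n  absorbed %.6f\n  escaped  %.6f\n  cutoff   %.6f\n",
              l$emitted, l$retina, sum(l$absorbed), l$escaped, l$cutoff))
  cat(sprintf("  retinal hits: %d rays, %d interaction events\n",
              nrow(x$hits), x$n_events))
  invisible(x)
}
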