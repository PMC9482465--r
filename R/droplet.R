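# Random-packed liquid droplet configurations.
#
# The droplet is the structural model behind the liquid-phase diffraction
# basis: n rigid copies of a template molecule with uniformly random
# orientations, packed into a sphere whose radius is fixed by the target mass
# density, under a hard heavy-atom (non-hydrogen) contact constraint.
#
# Plain sequential rejection sampling jams well below liquid glycerol density
# (random sequential addition saturates around 38% packing fraction), so the
# packer seeds the sphere at reduced density by rejection sampling and then
# compresses radially (Jodrey-Tory style): shrink all centers towards the
# origin by a small factor, resolve any violated contacts by pushing the two
# molecules apart along their center line, and repeat until the target radius
# is reached with the hard constraint exactly satisfied.

.AVOGADRO <- 6.02214076e23

#' Pack rigid molecules into a spherical liquid droplet
#'
#' @param template A \code{mol_geometry}; rigid copies of it are packed.
#' @param n_molecules Number of copies (>= 1).
#' @param density Target mass density in g/cm^3; fixes the droplet radius via
#'   the template molar mass.
#' @param contact_distance Hard minimum intermolecular heavy-atom (non-H)
#'   distance in Angstrom.
#' @param seed Integer seed; the configuration is a pure function of the
#'   arguments.
#' @param max_attempts Maximum rejection-sampling attempts per molecule during
#'   seeding, and cap on compression sweeps; exceeded => error reporting the
#'   attempts made.
#' @param start_factor Initial radius inflation for the seeding stage.
#' @param shrink Radial shrink factor per compression step.
#' @return Object of class \code{liquid_config}: fields \code{molecules}
#'   (list of \code{mol_geometry}), \code{droplet_radius} (Angstrom),
#'   \code{target_density}, \code{contact_distance}, \code{seed},
#'   \code{template}.
#' @examples
#' cfg <- pack_droplet(build_glycerol(), n_molecules = 5, density = 1.26,
#'                     contact_distance = 3.2, seed = 1)
#' realized_density(cfg)
#' @export
pack_droplet <- function(template, n_molecules, density = 1.26,
                         contact_distance = 3.2, seed,
                         max_attempts = 20000L, start_factor = 1.35,
                         shrink = 0.985) {
  stopifnot(inherits(template, "mol_geometry"))
  if (n_molecules < 1L) stop("n_molecules must be >= 1")
  if (density <= 0) stop("density must be positive")
  if (contact_distance <= 0) stop("contact_distance must be positive")

  centered <- template
  centered$coords <- sweep(centered$coords, 2L, colMeans(centered$coords))
  heavy_idx <- which(centered$elements != "H")
  if (!length(heavy_idx)) heavy_idx <- seq_along(centered$elements)
  Hloc <- centered$coords[heavy_idx, , drop = FALSE]
  r_mol <- sqrt(max(rowSums(Hloc^2)))
  cutoff <- contact_distance + 2 * r_mol
  c2 <- contact_distance^2

  vol_A3 <- n_molecules * molar_mass(template) / (density * .AVOGADRO) * 1e24
  R_target <- (3 * vol_A3 / (4 * pi))^(1 / 3)

  old_seed <- .save_rng_state()
  on.exit(.restore_rng_state(old_seed), add = TRUE)
  set.seed(as.integer(seed))

  n <- as.integer(n_molecules)
  rots <- replicate(n, .random_rotation(), simplify = FALSE)
  # heavy atoms in body frame after rotation: array [n_heavy, 3, n]
  Hrot <- lapply(rots, function(Rm) Hloc %*% t(Rm))
  C <- matrix(0, n, 3L)

  # min squared heavy-atom distance between molecule a (center ca) and b
  pair_min_d2 <- function(Ha, ca, Hb, cb) {
    A <- sweep(Ha, 2L, ca, "+")
    B <- sweep(Hb, 2L, cb, "+")
    d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
    min(d2)
  }

  # --- seeding: rejection sampling in an inflated sphere ---
  R <- R_target * if (n == 1L) 1 else start_factor
  attempts_total <- 0L
  placed <- 0L
  while (placed < n) {
    att <- 0L
    repeat {
      att <- att + 1L
      attempts_total <- attempts_total + 1L
      if (att > max_attempts)
        stop(sprintf(paste0("droplet packing infeasible: molecule %d not placed ",
                            "after %d attempts (%d total)"),
                     placed + 1L, max_attempts, attempts_total))
      cand <- stats::runif(3L, -R, R)
      if (sum(cand^2) > R^2) next
      ok <- TRUE
      if (placed > 0L) {
        d_cc <- sqrt(colSums((t(C[seq_len(placed), , drop = FALSE]) - cand)^2))
        for (j in which(d_cc < cutoff)) {
          if (pair_min_d2(Hrot[[placed + 1L]], cand, Hrot[[j]], C[j, ]) < c2) {
            ok <- FALSE
            break
          }
        }
      }
      if (ok) break
    }
    placed <- placed + 1L
    C[placed, ] <- cand
  }

  # --- radial compression with pairwise push-apart ---
  if (n > 1L && R > R_target) {
    nh <- nrow(Hloc)
    Hstack <- do.call(rbind, Hrot)          # (n*nh) x 3, body frame
    molidx <- rep(seq_len(n), each = nh)
    off_i <- rep(seq_len(nh), each = nh)    # nh^2 atom-pair combinations
    off_j <- rep(seq_len(nh), times = nh)
    # candidate molecule pairs (com within cutoff) whose closest heavy-atom
    # pair violates the contact; returns cbind(a, b, min_distance)
    violating_pairs <- function() {
      D <- as.matrix(stats::dist(C))
      idx <- which(D < cutoff & upper.tri(D), arr.ind = TRUE)
      if (!nrow(idx)) return(NULL)
      m <- nrow(idx)
      AH <- Hstack + C[molidx, , drop = FALSE]
      ia <- rep((idx[, 1L] - 1L) * nh, each = nh * nh) + rep(off_i, times = m)
      ib <- rep((idx[, 2L] - 1L) * nh, each = nh * nh) + rep(off_j, times = m)
      d2 <- rowSums((AH[ia, , drop = FALSE] - AH[ib, , drop = FALSE])^2)
      pmin2 <- apply(matrix(d2, nrow = nh * nh), 2L, min)
      keep <- pmin2 < c2
      if (!any(keep)) return(NULL)
      cbind(idx[keep, , drop = FALSE], sqrt(pmin2[keep]))
    }
    sweeps <- 0L
    repeat {
      R_new <- max(R_target, R * shrink)
      C <- C * (R_new / R)
      R <- R_new
      for (pass in seq_len(300L)) {
        bad <- violating_pairs()
        if (is.null(bad)) break
        a <- bad[, 1L]; b <- bad[, 2L]
        V <- C[a, , drop = FALSE] - C[b, , drop = FALSE]
        nv <- sqrt(rowSums(V^2))
        deg <- nv < 1e-9
        if (any(deg)) {
          V[deg, ] <- matrix(stats::rnorm(3L * sum(deg)), ncol = 3L)
          nv[deg] <- sqrt(rowSums(V[deg, , drop = FALSE]^2))
        }
        push <- (contact_distance - bad[, 3L]) * 0.55 + 0.005
        U <- V / nv * push
        disp <- rowsum(rbind(U, -U), group = c(a, b))
        who <- as.integer(rownames(disp))
        C[who, ] <- C[who, , drop = FALSE] + disp
        rad <- sqrt(rowSums(C^2))
        out <- rad > R
        if (any(out)) C[out, ] <- C[out, , drop = FALSE] * (R / rad[out])
      }
      sweeps <- sweeps + 1L
      if (R <= R_target && is.null(violating_pairs())) break
      if (sweeps > max_attempts)
        stop(sprintf(paste0("droplet packing infeasible: compression stalled ",
                            "after %d sweeps at radius %.2f (target %.2f)"),
                     sweeps, R, R_target))
    }
  }

  molecules <- vector("list", n)
  for (i in seq_len(n)) {
    g <- centered
    g$coords <- centered$coords %*% t(rots[[i]])
    g$coords <- sweep(g$coords, 2L, C[i, ], "+")
    g$name <- sprintf("%s[%d]", template$name, i)
    molecules[[i]] <- g
  }
  structure(list(molecules = molecules, droplet_radius = R_target,
                 target_density = density, contact_distance = contact_distance,
                 seed = as.integer(seed), template = template),
            class = "liquid_config")
}

#' @export
print.liquid_config <- function(x, ...) {
  cat(sprintf("<liquid_config> %d x %s, R = %.2f A, rho = %.3f g/cm^3, seed %d\n",
              length(x$molecules), x$template$name, x$droplet_radius,
              x$target_density, x$seed))
  invisible(x)
}

#' Flatten a liquid configuration to a single geometry
#'
#' The flattened atom set is what the molecular (Debye) interference sum runs
#' over for the liquid phase: every intra- and intermolecular pair.
#'
#' @param config A \code{liquid_config}.
#' @return A \code{mol_geometry} with \code{n_molecules * n_atoms(template)}
#'   atoms.
#' @export
flatten_config <- function(config) {
  stopifnot(inherits(config, "liquid_config"))
  elements <- unlist(lapply(config$molecules, `[[`, "elements"))
  coords <- do.call(rbind, lapply(config$molecules, `[[`, "coords"))
  molecular_geometry(elements, coords,
                     name = sprintf("droplet(%s x %d)",
                                    config$template$name,
                                    length(config$molecules)),
                     check = FALSE)
}

#' Realized mass density of a packed droplet
#' @param config A \code{liquid_config}.
#' @return Density in g/cm^3 (total mass over the nominal droplet volume).
#' @export
realized_density <- function(config) {
  stopifnot(inherits(config, "liquid_config"))
  mass_g <- length(config$molecules) * molar_mass(config$template) / .AVOGADRO
  vol_cm3 <- 4 / 3 * pi * config$droplet_radius^3 * 1e-24
  mass_g / vol_cm3
}

#' Center-of-mass positions of the packed molecules
#' @param config A \code{liquid_config}.
#' @return Matrix (n_molecules x 3) of unweighted centroid positions, Angstrom.
#' @export
molecule_centers <- function(config) {
  t(vapply(config$molecules, function(g) colMeans(g$coords), numeric(3L)))
}

# RNG bookkeeping: seeded operations must not disturb the caller's stream
.save_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
}
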