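#' Specification of a synthetic toy capsid family
#'
#' Describes a seeded family of coarse C-alpha-bead capsids with planted
#' ground truth: which residues touch a symmetry neighbour after assembly
#' (`planted_interface`), which alignment columns are strictly conserved
#' (`planted_seq_conserved`), and which interface residues keep the same
#' angular map position across members (`planted_space_conserved`, a subset
#' of the interface set). Everything else is randomized: non-conserved
#' columns differ between members and non-space-conserved interface residues
#' are displaced well beyond twice the overlap threshold.
#'
#' @param n_members number of family members (>= 2 for map alignment).
#' @param t_number 1 (one chain per asymmetric unit) or 3 (three chains).
#' @param residues_per_chain chain length.
#' @param planted_interface integer residue indices planted at a 2-fold axis.
#' @param planted_seq_conserved integer residue indices with identical
#'   alignment columns.
#' @param planted_space_conserved subset of `planted_interface` co-located
#'   across members within `angular_noise`.
#' @param angular_noise degrees; keep below the 3-degree overlap threshold.
#' @param displacement degrees by which non-space-conserved interface
#'   residues are shifted between members (> 2x the threshold).
#' @param seed RNG seed.
#' @return a `toy_family_spec`.
#' @export
toy_family_spec <- function(n_members = 4, t_number = 3, residues_per_chain = 30,
                            planted_interface = c(5, 9, 14, 21),
                            planted_seq_conserved = c(3, 9, 14, 26),
                            planted_space_conserved = c(9, 14, 21),
                            angular_noise = 1.0, displacement = 7.0,
                            seed = 42) {
  if (!t_number %in% c(1, 3)) stop("t_number must be 1 or 3")
  n_planted <- length(planted_interface)
  if (max(planted_interface, planted_seq_conserved) > residues_per_chain) {
    stop("planted residue index exceeds chain length")
  }
  if (!all(planted_space_conserved %in% planted_interface)) {
    stop("planted_space_conserved must be a subset of planted_interface")
  }
  if (angular_noise < 0) stop("angular_noise must be >= 0")
  if (displacement <= 6) stop("displacement must exceed twice the 3-degree threshold")
  if (n_planted > 9) stop("at most 9 interface residues fit the planted 2-fold band")
  structure(list(n_members = n_members, t_number = t_number,
                 residues_per_chain = residues_per_chain,
                 planted_interface = sort(planted_interface),
                 planted_seq_conserved = sort(planted_seq_conserved),
                 planted_space_conserved = sort(planted_space_conserved),
                 angular_noise = angular_noise, displacement = displacement,
                 seed = seed),
            class = "toy_family_spec")
}

# deterministic sunflower layout of k points near a central direction
# (psi0, phi0), spread within `radius_deg` angularly and stepped radially so
# consecutive beads form a loose chain; radial separation guarantees that
# beads of different shells can never touch any symmetry image of the other
cluster_positions <- function(k, psi0, phi0, radius_deg, r0, dr) {
  gold <- pi * (3 - sqrt(5))
  t <- seq_len(k)
  rho <- radius_deg * sqrt(t / k) * pi / 180
  th <- (t - 1) * gold
  psi <- psi0 * pi / 180 + rho * cos(th)
  phi <- phi0 * pi / 180 + rho * sin(th) / sin(psi0 * pi / 180)
  r <- r0 + dr * (t - 1)
  cbind(r * sin(psi) * cos(phi), r * sin(psi) * sin(phi), r * cos(psi))
}

toy_bands <- list(A = 15, B = 135, C = 255)  # planted-bead band start azimuth
# anchor direction for non-interface beads: numerically the direction whose
# icosahedral orbit has maximal self-separation (~26.6 degrees); chains are
# stacked on distinct radial shells so cross-chain image contacts are
# impossible by construction
toy_anchor <- c(psi = 36, phi = 8)
toy_shell_r0 <- c(A = 44, B = 60, C = 76)

#' Generate a synthetic toy capsid family with planted ground truth
#'
#' Builds `n_members` asymmetric units of C-alpha bead chains on a sphere of
#' radius 50 Angstrom. Planted interface residues sit 1.9 Angstrom from the
#' z 2-fold axis, so after assembly each is 3.8 Angstrom from its own
#' symmetry image (inside the 4.5 Angstrom contact cutoff) while all other
#' beads stay far from every image. Planted space-conserved residues keep
#' their azimuth across members to within `angular_noise`; other interface
#' residues are displaced by `displacement` degrees with alternating sign.
#' Aligned sequences (no gaps) carry the planted conserved columns.
#'
#' The generator verifies its own plant: after assembling each member it
#' checks by direct distance computation that exactly the planted residues
#' have a cross-subunit neighbour within the cutoff.
#'
#' @param spec a [toy_family_spec()].
#' @param cutoff contact cutoff the plant is built against (Angstrom).
#' @param radius capsid radius, Angstrom.
#' @return list with `members` (each: `au`, `sequence`, `virus_id`), `truth`
#'   (`interface`, `seq_conserved`, `space_conserved`, `hot_spots`), and the
#'   `spec`.
#' @export
make_toy_family <- function(spec, cutoff = 4.5, radius = 50) {
  stopifnot(inherits(spec, "toy_family_spec"))
  set.seed(spec$seed)
  n_chains <- if (spec$t_number == 3) 3 else 1
  classes <- LETTERS[seq_len(n_chains)]
  n <- spec$residues_per_chain
  planted <- spec$planted_interface
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

  # aligned sequences: conserved columns share one letter, all others are
  # guaranteed polymorphic (member 2 forced to differ from member 1)
  cons_letter <- sample(aa, n, replace = TRUE)
  seqs <- matrix("", spec$n_members, n)
  for (j in seq_len(n)) {
    if (j %in% spec$planted_seq_conserved) {
      seqs[, j] <- cons_letter[j]
    } else {
      seqs[, j] <- sample(aa, spec$n_members, replace = TRUE)
      if (spec$n_members >= 2) seqs[2, j] <- sample(setdiff(aa, seqs[1, j]), 1)
    }
  }

  # per-member azimuth of each planted bead, per chain class
  p_rank <- seq_along(planted)
  members <- vector("list", spec$n_members)
  for (m in seq_len(spec$n_members)) {
    subunits <- list()
    for (ci in seq_len(n_chains)) {
      cls <- classes[ci]
      alpha_ref <- toy_bands[[cls]] + 4 * (p_rank - 1)
      alpha <- alpha_ref
      for (p in p_rank) {
        r <- planted[p]
        if (m > 1) {
          if (r %in% spec$planted_space_conserved) {
            alpha[p] <- alpha_ref[p] + stats::runif(1, -1, 1) * spec$angular_noise
          } else {
            alpha[p] <- alpha_ref[p] +
              ifelse(p %% 2 == 0, 1, -1) * (spec$displacement + stats::runif(1, 0, 1.5))
          }
        }
      }
      xyz <- matrix(NA_real_, n, 3)
      rho <- 1.9
      z0 <- sqrt(radius^2 - rho^2) - 4
      xyz[planted, ] <- cbind(rho * cos(alpha * pi / 180),
                              rho * sin(alpha * pi / 180),
                              z0 + 0.9 * (p_rank - 1))
      rest <- setdiff(seq_len(n), planted)
      if (length(rest)) {
        xyz[rest, ] <- cluster_positions(length(rest), psi0 = toy_anchor[["psi"]],
                                         phi0 = toy_anchor[["phi"]],
                                         radius_deg = 1.5,
                                         r0 = toy_shell_r0[[cls]], dr = 0.4)
      }
      atoms <- data.frame(serial = seq_len(n), name = "CA", element = "C",
                          x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                          occ = 1, is_heavy = TRUE, resno = seq_len(n),
                          ins = "", resid = "ALA", stringsAsFactors = FALSE)
      subunits[[ci]] <- new_subunit(label = cls, source_chain = cls, atoms = atoms)
    }
    vid <- sprintf("toy%02d", m)
    au <- new_asym_unit(subunits, virus_id = vid)
    verify_plant(au, planted, cutoff)
    members[[m]] <- list(au = au, sequence = paste(seqs[m, ], collapse = ""),
                         virus_id = vid)
  }
  names(members) <- vapply(members, `[[`, "", "virus_id")
  truth <- list(interface = planted,
                seq_conserved = spec$planted_seq_conserved,
                space_conserved = spec$planted_space_conserved,
                hot_spots = sort(intersect(spec$planted_space_conserved,
                                           spec$planted_seq_conserved)))
  list(members = members, truth = truth, spec = spec)
}

# direct (non-pipeline) check that exactly the planted residues contact a
# symmetry image after assembly
verify_plant <- function(au, planted, cutoff) {
  grp <- generate_group()
  for (ci in seq_along(au$subunits)) {
    x0 <- as.matrix(au$subunits[[ci]]$atoms[, c("x", "y", "z")])
    mind <- rep(Inf, nrow(x0))
    for (cj in seq_along(au$subunits)) {
      xj <- as.matrix(au$subunits[[cj]]$atoms[, c("x", "y", "z")])
      for (k in seq_along(grp$operators)) {
        if (k == 1 && ci == cj) next  # same subunit copy
        img <- xj %*% t(grp$operators[[k]])
        d2 <- outer(rowSums(x0^2), rowSums(img^2), "+") - 2 * x0 %*% t(img)
        mind <- pmin(mind, sqrt(pmax(0, apply(d2, 1, min))))
      }
    }
    in_contact <- which(mind <= cutoff)
    if (!setequal(in_contact, planted)) {
      stop(sprintf(paste0("toy geometry inconsistent for chain %s: contacts ",
                          "at [%s], planted [%s]"),
                   au$subunits[[ci]]$label,
                   paste(in_contact, collapse = ","),
                   paste(planted, collapse = ",")))
    }
    margin <- min(mind[-planted])
    if (margin < cutoff + 0.5) {
      stop(sprintf("toy geometry margin too small (%.2f A) for chain %s",
                   margin, au$subunits[[ci]]$label))
    }
  }
  invisible(TRUE)
}

#' Specification of a synthetic 1D potential
#'
#' Known analytic potentials used as exact oracles for the umbrella/WHAM
#' machinery. The `morse` form is a binding-shaped profile with well depth
#' `depth` at `xi0` and a zero plateau at large separation; `double_well` has
#' two minima at `xi0 +/- width` separated by a barrier of height `barrier`;
#' `harmonic` is a single quadratic well.
#'
#' @param form `"morse"`, `"double_well"` or `"harmonic"`.
#' @param depth well depth, kcal/mol (morse).
#' @param xi0 minimum location, nm.
#' @param width length scale, nm.
#' @param barrier barrier height, kcal/mol (double_well).
#' @param k_harm harmonic constant, kcal/mol/nm^2.
#' @param support xi interval covered by the inverse-CDF grid, nm.
#' @param temperature K.
#' @return a `potential_spec` with an evaluation function `U(xi)` (kcal/mol).
#' @export
potential_spec <- function(form = c("morse", "double_well", "harmonic"),
                           depth = 5, xi0 = 1.0, width = 0.5, barrier = 2,
                           k_harm = 10, support = NULL, temperature = 300) {
  form <- match.arg(form)
  U <- switch(form,
    morse = function(x) depth * ((1 - exp(-(x - xi0) / width))^2 - 1),
    double_well = function(x) barrier * (((x - xi0)^2 - width^2) / width^2)^2,
    harmonic = function(x) 0.5 * k_harm * (x - xi0)^2)
  support <- support %||% switch(form,
    morse = c(xi0 - 0.9 * width, xi0 + 14 * width),
    double_well = c(xi0 - 3 * width, xi0 + 3 * width),
    harmonic = c(xi0 - 5, xi0 + 5))
  structure(list(form = form, depth = depth, xi0 = xi0, width = width,
                 barrier = barrier, k_harm = k_harm, support = support,
                 temperature = temperature, U = U),
            class = "potential_spec")
}

#' Evenly spaced umbrella windows over an interval
#'
#' @param from,to window center range, nm.
#' @param n number of windows.
#' @param spring_k spring constant, kJ/mol/nm^2 (default 2000, a typical
#'   pulling value).
#' @return list of [bias_potential()].
#' @export
make_umbrella_windows <- function(from, to, n, spring_k = 2000) {
  lapply(seq(from, to, length.out = n), bias_potential, spring_k = spring_k)
}

#' Draw umbrella-window samples exactly from a known potential
#'
#' For each window the biased Boltzmann density `exp(-(U + w_j)/k_BT)` is
#' tabulated on a fine grid over the potential's support and sampled by
#' inverse CDF (piecewise-linear within grid cells), so the samples carry no
#' Markov-chain error: the only deviation from the target density is the
#' grid discretization, which is negligible next to sampling noise.
#'
#' @param pot a [potential_spec()].
#' @param biases list of [bias_potential()].
#' @param n_samples samples per window.
#' @param seed RNG seed.
#' @param grid_n grid resolution (default 10000).
#' @return list of `window_series`.
#' @export
sample_umbrella <- function(pot, biases, n_samples, seed = 1, grid_n = 10000L) {
  set.seed(seed)
  kbt <- KB_KCAL * pot$temperature
  x <- seq(pot$support[1], pot$support[2], length.out = grid_n)
  dx <- x[2] - x[1]
  Ux <- pot$U(x)
  lapply(seq_along(biases), function(j) {
    b <- biases[[j]]
    logd <- -(Ux + b$energy(x)) / kbt
    mx <- max(logd)
    if (!is.finite(mx)) stop(sprintf("window %d: biased density underflows everywhere", j))
    d <- exp(logd - mx)
    p <- d / sum(d)
    cells <- sample.int(grid_n, n_samples, replace = TRUE, prob = p)
    s <- x[cells] + stats::runif(n_samples, -dx / 2, dx / 2)
    new_window_series(window_id = j, center = b$center, spring_k = b$spring_k,
                      samples = s, temperature = pot$temperature)
  })
}
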