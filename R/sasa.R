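#' Van der Waals radii used for surface-area calculations
#'
#' Bondi-type radii (Angstrom) for the elements common in protein structures.
#' Unknown elements raise an error rather than receiving a silent default.
#' @format named numeric vector, Angstrom.
#' @export
vdw_radii <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80,
               P = 1.80, SE = 1.90, F = 1.47, CL = 1.75, BR = 1.85,
               I = 1.98, ZN = 1.39, MG = 1.73, CA = 2.31, FE = 1.52,
               MN = 1.61, "NA" = 2.27, K = 2.75)

# deterministic, nearly uniform unit-sphere points (golden-spiral lattice)
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  th <- (seq_len(n) - 1) * pi * (3 - sqrt(5))
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(th), r * sin(th), z)
}

#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' Sphere-point SASA over the heavy atoms of one or several subunits treated
#' as a single complex. Each atom's accessible sphere (radius = vdW + probe)
#' is sampled on a deterministic golden-spiral lattice; a point is accessible
#' when it lies outside the accessible sphere of every other atom. Per-residue
#' SASA is the sum over the residue's heavy atoms.
#'
#' @param subunits a `capsid_subunit`, list thereof, or an `asym_unit`.
#' @param probe probe radius, Angstrom (1.4 = water).
#' @param n_points sphere points per atom; 960 gives ~1% accuracy.
#' @return data.frame with columns `subunit`, `resno`, `ins`, `resid`,
#'   `sasa` (Angstrom^2).
#' @export
compute_sasa <- function(subunits, probe = 1.4, n_points = 960) {
  if (inherits(subunits, "asym_unit")) subunits <- subunits$subunits
  if (inherits(subunits, "capsid_subunit")) subunits <- list(subunits)
  at <- do.call(rbind, lapply(subunits, function(s) {
    a <- s$atoms[s$atoms$is_heavy, , drop = FALSE]
    if (nrow(a)) a$subunit <- s$label
    a
  }))
  if (is.null(at) || nrow(at) == 0) stop("no heavy atoms")
  el <- toupper(at$element)
  unknown <- setdiff(unique(el), names(vdw_radii))
  if (length(unknown)) {
    stop("no vdW radius for element(s): ", paste(unknown, collapse = ", "),
         " (atoms ", paste(utils::head(at$serial[el %in% unknown], 5), collapse = ","), ")")
  }
  r <- vdw_radii[el] + probe
  xyz <- as.matrix(at[, c("x", "y", "z")])
  sp <- sphere_points(n_points)
  n <- nrow(xyz)
  area <- numeric(n)
  # neighbour lists via a coarse distance prefilter
  maxr <- max(r)
  for (a in seq_len(n)) {
    d2 <- (xyz[, 1] - xyz[a, 1])^2 + (xyz[, 2] - xyz[a, 2])^2 +
      (xyz[, 3] - xyz[a, 3])^2
    nb <- which(d2 < (r[a] + maxr)^2 & seq_len(n) != a)
    nb <- nb[d2[nb] < (r[a] + r[nb])^2]
    if (length(nb) == 0) {
      area[a] <- 4 * pi * r[a]^2
      next
    }
    pts <- sweep(sp * r[a], 2, xyz[a, ], "+")
    acc <- rep(TRUE, n_points)
    for (b in nb) {
      if (!any(acc)) break
      keep <- which(acc)
      db <- (pts[keep, 1] - xyz[b, 1])^2 + (pts[keep, 2] - xyz[b, 2])^2 +
        (pts[keep, 3] - xyz[b, 3])^2
      acc[keep[db < r[b]^2]] <- FALSE
    }
    area[a] <- 4 * pi * r[a]^2 * sum(acc) / n_points
  }
  key <- paste(at$subunit, at$resno, at$ins, sep = "|")
  agg <- rowsum(area, key)
  first <- which(!duplicated(key))
  data.frame(subunit = at$subunit[first], resno = at$resno[first],
             ins = at$ins[first], resid = at$resid[first],
             sasa = as.numeric(agg[match(key[first], rownames(agg)), 1]),
             stringsAsFactors = FALSE)
}

#' Geometric profile of one residue in a dimer context
#'
#' Computes the complexed and isolated solvent-accessible surface area of a
#' residue, the buried surface area (BSA = isolated - complexed, clamped at
#' zero; values below -0.5 A^2 indicate an inconsistency and raise an error),
#' and the number of distinct partner residues in close contact (NumInt).
#'
#' @param subunit_a,subunit_b the two `capsid_subunit`s of the complex.
#' @param resno residue number (in `subunit_a`).
#' @param criterion a [contact_criterion()].
#' @param probe,n_points SASA parameters, see [compute_sasa()].
#' @return a `residue_profile`: list with `resno`, `resid`, `sasa_complex`,
#'   `sasa_isolated`, `bsa` (Angstrom^2) and `num_contacts`.
#' @export
residue_profile <- function(subunit_a, subunit_b, resno,
                            criterion = contact_criterion(),
                            probe = 1.4, n_points = 960) {
  if (!resno %in% subunit_a$atoms$resno) {
    stop(sprintf("residue %s not found in subunit %s", resno, subunit_a$label))
  }
  sel <- function(df) df[df$subunit == subunit_a$label & df$resno == resno, ]
  s_cplx <- sel(compute_sasa(list(subunit_a, subunit_b), probe, n_points))
  s_iso <- sel(compute_sasa(subunit_a, probe, n_points))
  bsa <- sum(s_iso$sasa) - sum(s_cplx$sasa)
  if (bsa < -0.5) stop("negative buried area beyond discretization error")
  pairs <- find_interfaces(list(subunit_a, subunit_b), criterion)
  nint <- 0L
  if (length(pairs)) {
    ri <- pairs[[1]]$residues_i
    row <- ri[ri$resno == resno, ]
    if (nrow(row)) nint <- row$n_contact_res[1]
  }
  structure(list(resno = resno,
                 resid = subunit_a$atoms$resid[match(resno, subunit_a$atoms$resno)],
                 sasa_complex = sum(s_cplx$sasa), sasa_isolated = sum(s_iso$sasa),
                 bsa = max(0, bsa), num_contacts = nint),
            class = "residue_profile")
}
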