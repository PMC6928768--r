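#' Project a point to capsid-map angular coordinates
#'
#' Converts Cartesian coordinates (relative to the capsid center) to the
#' spherical angles used by angular capsid maps: `psi = acos(z/|v|)` in
#' `[0, 180]` (colatitude) and `phi = atan2(y, x)` mapped to `[-180, 180)`
#' (azimuth), both in degrees. The radial distance is discarded, so the map
#' depends only on direction. Points on the z axis take `phi = 0` by
#' convention.
#'
#' @param coords numeric(3) or n x 3 matrix, Angstrom.
#' @param center capsid center (default origin).
#' @return data.frame with columns `phi`, `psi` (degrees).
#' @export
#' @examples
#' project_point(c(0, 0, 10))      # pole: psi 0
#' project_point(c(5, 5, 0))       # phi 45, psi 90
project_point <- function(coords, center = c(0, 0, 0)) {
  v <- if (is.matrix(coords)) sweep(coords, 2, center) else
    matrix(coords - center, ncol = 3)
  r <- sqrt(rowSums(v^2))
  if (any(r < 1e-9)) stop("point coincides with the capsid center")
  psi <- acos(pmax(-1, pmin(1, v[, 3] / r))) * 180 / pi
  rho <- sqrt(v[, 1]^2 + v[, 2]^2)
  phi <- ifelse(rho < 1e-12, 0, atan2(v[, 2], v[, 1]) * 180 / pi)
  phi[phi >= 180] <- phi[phi >= 180] - 360
  data.frame(phi = phi, psi = psi)
}

#' Representative point of a residue
#'
#' Geometric center of the side-chain heavy atoms; falls back to the alpha
#' carbon for glycine (or any residue without side-chain heavy atoms), and to
#' the heavy-atom centroid for non-standard residues without a CA.
#'
#' @param atoms atom data.frame of one residue.
#' @param mode `"sidechain"` (default) or `"ca"`.
#' @return numeric(3).
#' @export
residue_point <- function(atoms, mode = c("sidechain", "ca")) {
  mode <- match.arg(mode)
  heavy <- atoms[atoms$is_heavy, , drop = FALSE]
  if (nrow(heavy) == 0) stop("residue has no heavy atoms")
  nm <- trimws(heavy$name)
  if (mode == "ca") {
    ca <- heavy[nm == "CA", , drop = FALSE]
    if (nrow(ca)) return(c(ca$x[1], ca$y[1], ca$z[1]))
    return(colMeans(heavy[, c("x", "y", "z")]))
  }
  sc <- heavy[!nm %in% c("N", "CA", "C", "O", "OXT"), , drop = FALSE]
  if (nrow(sc) == 0) return(residue_point(atoms, "ca"))
  colMeans(sc[, c("x", "y", "z")])
}

#' Build the angular capsid map of an asymmetric unit's interface residues
#'
#' One map point per interface residue per asymmetric-unit chain: the
#' residue's representative point projected to (phi, psi). Maps built from
#' structures in the same standard icosahedral orientation are directly
#' comparable across viruses.
#'
#' @param au an `asym_unit`.
#' @param interface_residues named list: class letter -> integer vector of
#'   interface residue numbers (e.g. from [interface_residue_union()]); a
#'   bare integer vector is taken to refer to the first chain.
#' @param point_mode `"sidechain"` or `"ca"`, see [residue_point()].
#' @param center capsid center.
#' @param orientation_tag orientation label carried for comparability checks.
#' @return a `capsid_map`: list with `virus_id`, `orientation_tag`, `points`
#'   (data.frame chain/resno/resid/phi/psi).
#' @export
build_capsidmap <- function(au, interface_residues, point_mode = "sidechain",
                            center = c(0, 0, 0), orientation_tag = "222") {
  if (!is.list(interface_residues)) {
    interface_residues <- stats::setNames(list(interface_residues), "A")
  }
  rows <- list()
  for (ci in seq_along(au$subunits)) {
    letter <- LETTERS[ci]
    want <- interface_residues[[letter]]
    if (is.null(want) || length(want) == 0) next
    at <- au$subunits[[ci]]$atoms
    for (rn in sort(unique(want))) {
      ra <- at[at$resno == rn, , drop = FALSE]
      if (nrow(ra) == 0) next
      p <- residue_point(ra, point_mode)
      ang <- project_point(p, center)
      rows[[length(rows) + 1]] <- data.frame(
        chain = letter, resno = rn, resid = ra$resid[1],
        phi = ang$phi, psi = ang$psi, stringsAsFactors = FALSE)
    }
  }
  pts <- if (length(rows)) do.call(rbind, rows) else
    data.frame(chain = character(0), resno = integer(0), resid = character(0),
               phi = numeric(0), psi = numeric(0))
  structure(list(virus_id = au$virus_id, orientation_tag = orientation_tag,
                 points = pts), class = "capsid_map")
}

#' @export
print.capsid_map <- function(x, ...) {
  cat(sprintf("CapsidMap '%s' (%s): %d interface residue point(s)\n",
              x$virus_id, x$orientation_tag, nrow(x$points)))
  invisible(x)
}

#' Export a capsid map as TSV
#' @param map a `capsid_map`.
#' @param path optional output path.
#' @return data.frame (invisibly if written).
#' @export
export_capsidmap <- function(map, path = NULL) {
  df <- cbind(virus = map$virus_id, map$points)
  if (!is.null(path)) {
    utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
    return(invisible(df))
  }
  df
}

#' Strictly conserved alignment columns and their residue numbers
#'
#' Finds columns where all sequences carry the same residue with no gaps and
#' maps each such column to per-virus author residue numbers by counting
#' non-gap positions against a per-virus numbering offset (the author number
#' of the first non-gap residue).
#'
#' @param aln an `alignment_set`.
#' @param offsets named integer vector, virus -> author number of the first
#'   residue; defaults to 1 for every virus.
#' @return list with `columns` (integer vector) and `residue_numbers` (named
#'   list virus -> integer vector parallel to `columns`).
#' @export
conserved_columns <- function(aln, offsets = NULL) {
  seqs <- aln$sequences
  if (is.null(offsets)) offsets <- stats::setNames(rep(1L, length(seqs)), names(seqs))
  miss <- setdiff(names(seqs), names(offsets))
  if (length(miss)) stop("no numbering offset for: ", paste(miss, collapse = ", "))
  mat <- do.call(rbind, strsplit(seqs, ""))
  cons <- apply(mat, 2, function(col) all(col == col[1]) && col[1] != "-")
  cols <- which(cons)
  resmap <- msa_residue_map(aln, offsets)
  residue_numbers <- lapply(names(seqs), function(v) {
    unname(resmap[[v]][cols])
  })
  names(residue_numbers) <- names(seqs)
  list(columns = cols, residue_numbers = residue_numbers)
}

#' Alignment column to residue-number correspondence
#'
#' @param aln an `alignment_set`.
#' @param offsets named integer vector as in [conserved_columns()].
#' @return named list: virus -> integer vector of length `n_columns` with the
#'   author residue number at each column (`NA` at gaps).
#' @export
msa_residue_map <- function(aln, offsets = NULL) {
  seqs <- aln$sequences
  if (is.null(offsets)) offsets <- stats::setNames(rep(1L, length(seqs)), names(seqs))
  out <- lapply(names(seqs), function(v) {
    ch <- strsplit(seqs[[v]], "")[[1]]
    nongap <- ch != "-"
    num <- rep(NA_integer_, length(ch))
    num[nongap] <- offsets[[v]] + seq_len(sum(nongap)) - 1L
    num
  })
  names(out) <- names(seqs)
  out
}

circ_diff <- function(a, b) {
  d <- (a - b) %% 360
  pmin(d, 360 - d)
}

#' Space-conserved residues across aligned capsid maps
#'
#' A residue of the reference virus is conserved in quaternary-structure
#' position when, for every other family member (or a quorum of them), the
#' alignment-corresponding residue is present in that member's map for the
#' same quasi-equivalent chain class and its angular position agrees within
#' the overlap threshold in both angles (`|d phi| <= t` and `|d psi| <= t`,
#' phi compared on the circle). The default threshold is 3 degrees.
#'
#' @param maps named list of `capsid_map` (names = virus ids); the first (or
#'   `reference`) defines the reported numbering.
#' @param correspondence output of [msa_residue_map()] covering all viruses.
#' @param angle_threshold degrees (default 3).
#' @param require_all_members if `TRUE` (default) every other member must
#'   match; otherwise `quorum` applies.
#' @param quorum fraction of other members that must match when
#'   `require_all_members = FALSE`.
#' @param reference virus id of the reference map (default first).
#' @return data.frame of conserved reference residues: `chain`, `resno`,
#'   `resid`, `phi`, `psi`.
#' @export
align_maps <- function(maps, correspondence, angle_threshold = 3,
                       require_all_members = TRUE, quorum = 0.5,
                       reference = NULL) {
  if (length(maps) < 2) stop("at least two capsid maps are required")
  if (angle_threshold <= 0) stop("angle_threshold must be > 0")
  tags <- unique(vapply(maps, `[[`, "", "orientation_tag"))
  if (length(tags) != 1) stop("maps have mismatched orientation tags: ",
                              paste(tags, collapse = ", "))
  if (is.null(names(maps))) names(maps) <- vapply(maps, `[[`, "", "virus_id")
  reference <- reference %||% names(maps)[1]
  ref <- maps[[reference]]
  others <- setdiff(names(maps), reference)
  col_of <- function(virus, resno) {
    hit <- which(correspondence[[virus]] == resno)
    if (length(hit)) hit[1] else NA_integer_
  }
  keep <- logical(nrow(ref$points))
  for (k in seq_len(nrow(ref$points))) {
    rp <- ref$points[k, ]
    colk <- col_of(reference, rp$resno)
    if (is.na(colk)) next
    ok <- vapply(others, function(v) {
      rn <- correspondence[[v]][colk]
      if (is.na(rn)) return(FALSE)
      mp <- maps[[v]]$points
      row <- mp[mp$chain == rp$chain & mp$resno == rn, , drop = FALSE]
      if (nrow(row) == 0) return(FALSE)
      any(circ_diff(row$phi, rp$phi) <= angle_threshold &
            abs(row$psi - rp$psi) <= angle_threshold)
    }, logical(1))
    keep[k] <- if (require_all_members) all(ok) else
      mean(ok) >= quorum
  }
  ref$points[keep, , drop = FALSE]
}

#' Predict structure-conserved hot spots
#'
#' The three-way intersection of (i) interface residues, (ii) strictly
#' sequence-conserved residues, and (iii) quaternary-position (space)
#' conserved residues, all in reference-virus numbering. Each hot spot is
#' annotated with the symmetry fold(s) of the interfaces it participates in
#' when a fold annotation table is supplied.
#'
#' @param interface_sets named list virus -> integer vector of interface
#'   residue numbers.
#' @param seq_conserved integer vector of sequence-conserved residue numbers
#'   in reference numbering (e.g. `conserved_columns()$residue_numbers[[ref]]`).
#' @param space_conserved data.frame from [align_maps()] (or integer vector).
#' @param reference reference virus id (must name an entry of
#'   `interface_sets`).
#' @param fold_annotation optional data.frame with columns `resno`, `fold`
#'   (from [export_interface_table()] of the reference virus).
#' @return a `hotspot_result`: list with the three sets and `hot_spots`
#'   (data.frame `resno`, `fold_class`).
#' @export
predict_hotspots <- function(interface_sets, seq_conserved, space_conserved,
                             reference = names(interface_sets)[1],
                             fold_annotation = NULL) {
  if (!reference %in% names(interface_sets)) {
    stop(sprintf("reference virus '%s' missing from interface sets", reference))
  }
  space <- if (is.data.frame(space_conserved)) sort(unique(space_conserved$resno))
  else sort(unique(space_conserved))
  hs <- sort(intersect(intersect(interface_sets[[reference]],
                                 sort(unique(seq_conserved))), space))
  fold <- rep(NA_character_, length(hs))
  if (!is.null(fold_annotation) && length(hs)) {
    fold <- vapply(hs, function(r) {
      f <- unique(fold_annotation$fold[fold_annotation$resno == r])
      if (length(f) == 0) NA_character_ else paste(sort(f), collapse = "/")
    }, character(1))
  }
  structure(list(interface_sets = interface_sets,
                 sequence_conserved = sort(unique(seq_conserved)),
                 space_conserved = space,
                 reference = reference,
                 hot_spots = data.frame(resno = hs, fold_class = fold,
                                        stringsAsFactors = FALSE)),
            class = "hotspot_result")
}

#' @export
print.hotspot_result <- function(x, ...) {
  cat(sprintf("Hot-spot prediction (reference %s)\n", x$reference))
  cat(sprintf("  interface residues (ref): %d\n",
              length(x$interface_sets[[x$reference]])))
  cat(sprintf("  sequence-conserved:       %d\n", length(x$sequence_conserved)))
  cat(sprintf("  space-conserved:          %d\n", length(x$space_conserved)))
  cat(sprintf("  hot spots:                %s\n",
              if (nrow(x$hot_spots)) paste(x$hot_spots$resno, collapse = ", ")
              else "(none)"))
  invisible(x)
}
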