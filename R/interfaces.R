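#' Contact criterion for interface detection
#'
#' A residue of one subunit is an interface residue of a pair when at least
#' one of its heavy atoms lies within `cutoff` of a heavy atom of the partner
#' subunit. 4.5 A is the conventional close-contact radius between heavy
#' atoms; it is exposed so database contact tables computed with other radii
#' can be matched.
#'
#' @param cutoff distance cutoff, Angstrom.
#' @param heavy_atoms_only restrict to heavy atoms (default TRUE).
#' @return a `contact_criterion`.
#' @export
contact_criterion <- function(cutoff = 4.5, heavy_atoms_only = TRUE) {
  if (cutoff <= 0) stop("cutoff must be > 0")
  structure(list(cutoff = cutoff, heavy_atoms_only = heavy_atoms_only),
            class = "contact_criterion")
}

#' Atom pairs within a cutoff between two coordinate sets
#'
#' Both an exhaustive all-pairs route and a cell-list (spatial hashing) route
#' are provided; they return identical pairs and the grid route is the
#' default for speed. Exported mainly so equivalence can be property-tested.
#'
#' @param xyz_i,xyz_j numeric matrices (n x 3).
#' @param cutoff distance cutoff.
#' @param method `"grid"` or `"brute"`.
#' @return two-column integer matrix of (row in i, row in j) index pairs.
#' @export
contact_pairs <- function(xyz_i, xyz_j, cutoff, method = c("grid", "brute")) {
  method <- match.arg(method)
  ni <- nrow(xyz_i); nj <- nrow(xyz_j)
  if (ni == 0 || nj == 0) return(matrix(integer(0), 0, 2))
  if (method == "brute") {
    d2 <- outer(rowSums(xyz_i^2), rowSums(xyz_j^2), "+") - 2 * xyz_i %*% t(xyz_j)
    hit <- which(d2 <= cutoff^2 + 1e-12, arr.ind = TRUE)
    return(unname(hit[order(hit[, 1], hit[, 2]), , drop = FALSE]))
  }
  # cell list: bin j atoms into cubic cells of edge = cutoff, look up the 27
  # neighbouring cells of each i atom
  cell <- function(m) floor(sweep(m, 2, rep(0, 3)) / cutoff)
  cj <- cell(xyz_j)
  keyj <- paste(cj[, 1], cj[, 2], cj[, 3], sep = ",")
  bucket <- split(seq_len(nj), keyj)
  ci <- cell(xyz_i)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  out_i <- integer(0); out_j <- integer(0)
  for (a in seq_len(ni)) {
    keys <- paste(ci[a, 1] + offs[, 1], ci[a, 2] + offs[, 2], ci[a, 3] + offs[, 3],
                  sep = ",")
    cand <- unlist(bucket[keys], use.names = FALSE)
    if (is.null(cand) || length(cand) == 0) next
    d2 <- (xyz_j[cand, 1] - xyz_i[a, 1])^2 + (xyz_j[cand, 2] - xyz_i[a, 2])^2 +
      (xyz_j[cand, 3] - xyz_i[a, 3])^2
    hit <- cand[d2 <= cutoff^2 + 1e-12]
    if (length(hit)) {
      out_i <- c(out_i, rep.int(a, length(hit)))
      out_j <- c(out_j, sort(hit))
    }
  }
  out <- cbind(out_i, out_j, deparse.level = 0)
  dimnames(out) <- NULL
  out
}

subunit_xyz <- function(s, heavy_only = TRUE) {
  a <- s$atoms
  if (heavy_only) a <- a[a$is_heavy, , drop = FALSE]
  list(xyz = as.matrix(a[, c("x", "y", "z")]),
       resno = a$resno, resid = a$resid, ins = a$ins)
}

#' Find interface residue pairs between subunits of a complex
#'
#' Scans subunit pairs of an assembly (or any multi-subunit complex) for
#' heavy-atom contacts within the criterion cutoff. Candidate subunit pairs
#' are pre-filtered with bounding spheres; within a pair a cell-list search is
#' used, which is exact (identical to the all-pairs computation). Pairs with
#' no contacting residues are omitted.
#'
#' @param assembly a `capsid_assembly`, `asym_unit`, or plain list of
#'   `capsid_subunit`.
#' @param criterion a [contact_criterion()].
#' @param focus optional character vector of subunit labels: only pairs with
#'   at least one member in `focus` are examined (e.g. the asymmetric-unit
#'   copies, to enumerate all their interfaces without scanning the whole
#'   shell against itself).
#' @return list of `interface_pair` objects: each has labels `subunit_i`,
#'   `subunit_j`, `fold_class` (via [classify_interface_fold()] when symmetry
#'   information is available, else `NA`), residue tables `residues_i`,
#'   `residues_j` (columns `resno`, `resid`, `n_contact_res`, `partners`),
#'   and the contact `centroid`.
#' @export
find_interfaces <- function(assembly, criterion = contact_criterion(),
                            focus = NULL) {
  subs <- if (inherits(assembly, "capsid_assembly") || inherits(assembly, "asym_unit"))
    assembly$subunits else assembly
  if (inherits(subs, "capsid_subunit")) subs <- list(subs)
  if (length(subs) == 0) stop("empty assembly")
  labels <- unname(vapply(subs, `[[`, "", "label"))
  names(subs) <- labels
  geo <- lapply(subs, subunit_xyz, heavy_only = criterion$heavy_atoms_only)
  nonempty <- vapply(geo, function(g) nrow(g$xyz) > 0, logical(1))
  ctr <- lapply(geo, function(g) if (nrow(g$xyz)) colMeans(g$xyz) else c(0, 0, 0))
  rad <- vapply(seq_along(geo), function(i) {
    if (!nonempty[i]) return(0)
    sqrt(max(rowSums(sweep(geo[[i]]$xyz, 2, ctr[[i]])^2)))
  }, numeric(1))
  n <- length(subs)
  if (is.null(focus)) {
    cand <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  } else {
    fi <- match(focus, labels)
    if (anyNA(fi)) stop("focus labels not in assembly: ",
                        paste(focus[is.na(fi)], collapse = ", "))
    cand <- unique(t(apply(
      rbind(as.matrix(expand.grid(fi, seq_len(n)))), 1, sort)))
    cand <- cand[cand[, 1] != cand[, 2], , drop = FALSE]
  }
  out <- list()
  for (r in seq_len(nrow(cand))) {
    i <- cand[r, 1]; j <- cand[r, 2]
    if (!nonempty[i] || !nonempty[j]) next
    dc <- sqrt(sum((ctr[[i]] - ctr[[j]])^2))
    if (dc > rad[i] + rad[j] + criterion$cutoff) next
    hits <- contact_pairs(geo[[i]]$xyz, geo[[j]]$xyz, criterion$cutoff)
    if (nrow(hits) == 0) next
    out[[length(out) + 1]] <- build_interface_pair(
      labels[i], labels[j], geo[[i]], geo[[j]], hits,
      if (inherits(assembly, "capsid_assembly")) assembly else NULL)
  }
  out
}

res_key <- function(resno, ins) paste0(resno, ifelse(nzchar(ins), ins, ""))

build_interface_pair <- function(li, lj, gi, gj, hits, assembly) {
  ri <- res_key(gi$resno[hits[, 1]], gi$ins[hits[, 1]])
  rj <- res_key(gj$resno[hits[, 2]], gj$ins[hits[, 2]])
  tab <- unique(data.frame(ri = ri, rj = rj, stringsAsFactors = FALSE))
  mk <- function(own, partner, g) {
    u <- unique(own)
    idx <- match(u, res_key(g$resno, g$ins))
    partners <- lapply(u, function(k) sort(unique(partner[own == k])))
    data.frame(resno = g$resno[idx], resid = g$resid[idx], ins = g$ins[idx],
               n_contact_res = vapply(partners, length, integer(1)),
               partners = I(partners), stringsAsFactors = FALSE)
  }
  residues_i <- mk(tab$ri, tab$rj, gi)
  residues_j <- mk(tab$rj, tab$ri, gj)
  centroid <- colMeans(rbind(gi$xyz[hits[, 1], , drop = FALSE],
                             gj$xyz[hits[, 2], , drop = FALSE]))
  pair <- structure(list(subunit_i = li, subunit_j = lj,
                         residues_i = residues_i, residues_j = residues_j,
                         centroid = centroid, fold_class = NA_character_),
                    class = "interface_pair")
  if (!is.null(assembly)) {
    pair$fold_class <- classify_interface_fold(pair, assembly)
  }
  pair
}

#' Classify an interface by capsid symmetry fold
#'
#' The fold class of an interface is the fold of the group operator relating
#' the two subunits. For subunits of the same quasi-equivalent class that
#' operator maps one subunit exactly onto the other and its fold is assigned
#' directly. For cross-class pairs the operator relates generating frames,
#' not the subunits themselves; the interface inherits its fold only when the
#' operator's rotation axis actually passes through the contact region
#' (axis-centroid angle below `axis_tol` degrees), otherwise the contact is
#' tagged `"quasi"` (the hexamer-style quasi-equivalent contacts).
#'
#' @param pair an `interface_pair` with a contact `centroid`.
#' @param assembly the `capsid_assembly` the pair came from.
#' @param axis_tol degrees; maximum angle between the relative operator's
#'   axis and the contact centroid direction for a cross-class fold call.
#' @return one of `"2-fold"`, `"3-fold"`, `"5-fold"`, `"quasi"`.
#' @export
classify_interface_fold <- function(pair, assembly, axis_tol = 20) {
  if (identical(pair$subunit_i, pair$subunit_j)) stop("no self-interface")
  rel <- relative_operator(assembly, pair$subunit_i, pair$subunit_j)
  gm <- assembly$generator_map
  cls_i <- gm$class[match(pair$subunit_i, gm$label)]
  cls_j <- gm$class[match(pair$subunit_j, gm$label)]
  if (rel$fold == "identity") {
    if (identical(cls_i, cls_j)) stop("subunits related by identity cannot form an interface")
    # contact between chains of one asymmetric-unit copy: no symmetry axis
    return("quasi")
  }
  if (identical(cls_i, cls_j)) return(rel$fold)
  u <- pair$centroid / sqrt(sum(pair$centroid^2))
  cosang <- abs(sum(u * rel$axis))
  ang <- acos(max(-1, min(1, cosang))) * 180 / pi
  if (ang <= axis_tol) rel$fold else "quasi"
}

#' Union of interface residues, mapped to asymmetric-unit numbering
#'
#' Collects all interface residues of the given quasi-equivalent class across
#' a set of interface pairs, deduplicated. Subunit labels are mapped back to
#' their class letter, so the union is in asymmetric-unit residue numbering.
#'
#' @param pairs list of `interface_pair`.
#' @param subunit_class class letter (`"A"`, `"B"`, ...).
#' @return sorted integer vector of residue numbers.
#' @export
interface_residue_union <- function(pairs, subunit_class = "A") {
  res <- integer(0)
  for (p in pairs) {
    if (substr(p$subunit_i, 1, 1) == subunit_class) res <- c(res, p$residues_i$resno)
    if (substr(p$subunit_j, 1, 1) == subunit_class) res <- c(res, p$residues_j$resno)
  }
  sort(unique(res))
}

#' Export interface pairs as a contact table
#'
#' One row per interface residue, mirroring database-style contact tables.
#'
#' @param pairs list of `interface_pair`.
#' @param virus_id identifier written in the first column.
#' @param path optional TSV output path.
#' @return data.frame (invisibly if written).
#' @export
export_interface_table <- function(pairs, virus_id = "", path = NULL) {
  rows <- list()
  for (p in pairs) {
    for (side in c("i", "j")) {
      rt <- p[[paste0("residues_", side)]]
      lab <- p[[paste0("subunit_", side)]]
      rows[[length(rows) + 1]] <- data.frame(
        virus = virus_id, pair = paste0(p$subunit_i, "-", p$subunit_j),
        fold = p$fold_class, subunit = lab, resno = rt$resno, resid = rt$resid,
        num_int = rt$n_contact_res, stringsAsFactors = FALSE)
    }
  }
  df <- do.call(rbind, rows)
  if (!is.null(path)) {
    utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
    return(invisible(df))
  }
  df
}
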