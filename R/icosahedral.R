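#' Rotation matrix about an arbitrary axis
#'
#' Rodrigues' formula. Used internally to build the icosahedral group from
#' generators.
#'
#' @param axis numeric(3), need not be normalized.
#' @param angle rotation angle in radians.
#' @return a 3x3 rotation matrix.
#' @export
rotation_about <- function(axis, angle) {
  u <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, u[3], -u[2],
                -u[3], 0, u[1],
                u[2], -u[1], 0), 3, 3)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

#' Classify a rotation operator by its symmetry fold
#'
#' The rotation angle follows from the trace (`tr = 1 + 2 cos(theta)`); for a
#' rotation in the icosahedral group the angle is one of 0, 72, 120, 144 or
#' 180 degrees, giving the identity, 5-fold, 3-fold, 5-fold and 2-fold classes
#' respectively. The rotation axis is the eigenvector of eigenvalue +1, with
#' sign fixed so the z component is positive (then x, then y on ties).
#'
#' @param m a 3x3 orthogonal matrix with determinant +1.
#' @param tol numerical tolerance for orthogonality and angle matching.
#' @return a list with elements `fold` (one of `"identity"`, `"2-fold"`,
#'   `"3-fold"`, `"5-fold"`), `angle_deg`, and `axis` (unit vector; `NA` for
#'   the identity).
#' @export
#' @examples
#' classify_operator(diag(3))$fold
#' classify_operator(rotation_about(c(0, 0, 1), pi))$fold
classify_operator <- function(m, tol = 1e-8) {
  stopifnot(is.matrix(m), all(dim(m) == c(3L, 3L)))
  if (max(abs(crossprod(m) - diag(3))) > sqrt(tol)) {
    stop("matrix is not orthogonal within tolerance")
  }
  if (abs(det(m) - 1) > 1e-6) stop("matrix is not a proper rotation (det != +1)")
  tr <- sum(diag(m))
  ct <- max(-1, min(1, (tr - 1) / 2))
  ang <- acos(ct) * 180 / pi
  folds <- c(identity = 0, `2-fold` = 180, `3-fold` = 120,
             `5-fold` = 72, `5-fold` = 144)
  k <- which.min(abs(folds - ang))
  if (abs(folds[k] - ang) > 1e-4) {
    stop(sprintf("rotation angle %.4f deg is not an icosahedral fold angle", ang))
  }
  fold <- names(folds)[k]
  if (fold == "identity") {
    return(list(fold = "identity", angle_deg = 0, axis = rep(NA_real_, 3)))
  }
  # axis: null space of (m - I); smallest singular vector
  sv <- svd(m - diag(3))
  axis <- sv$v[, 3]
  axis <- axis / sqrt(sum(axis^2))
  # sign convention: positive z, then positive x, then positive y
  s <- if (abs(axis[3]) > 1e-9) sign(axis[3]) else
    if (abs(axis[1]) > 1e-9) sign(axis[1]) else sign(axis[2])
  axis <- axis * s
  list(fold = unname(fold), angle_deg = unname(folds[k]), axis = axis)
}

#' Generate the 60-element icosahedral rotation group
#'
#' Builds the proper rotation group I (order 60) by closure from two
#' generators: a 5-fold rotation about an icosahedron vertex axis and a 2-fold
#' rotation about z, in the standard setting with the three mutually
#' perpendicular 2-fold axes on the coordinate axes (the icosahedral
#' convention used by structural virology databases). Building by closure
#' rather than from a hard-coded table makes the construction self-verifying:
#' the group order, closure and conjugacy-class sizes are all checked.
#'
#' @param orientation_tag name of the axis setting; only `"222"` (2-folds on
#'   x, y, z) is supported.
#' @param tol Frobenius tolerance for matching two operators as equal.
#' @return an object of class `icosa_group`: a list with `operators` (list of
#'   60 3x3 matrices, identity first), `fold` (character vector), `axis`
#'   (60 x 3 matrix) and `orientation_tag`.
#' @export
#' @examples
#' g <- generate_group()
#' length(g$operators)
#' table(g$fold)
generate_group <- function(orientation_tag = "222", tol = 1e-8) {
  if (!identical(orientation_tag, "222")) {
    stop(sprintf("unknown orientation_tag '%s' (supported: \"222\")", orientation_tag))
  }
  phi_g <- (1 + sqrt(5)) / 2
  gen5 <- rotation_about(c(0, 1, phi_g), 2 * pi / 5) # 5-fold through a vertex
  gen2 <- rotation_about(c(0, 0, 1), pi)             # 2-fold on z
  ops <- list(diag(3))
  frontier <- list(gen5, gen2)
  is_member <- function(m, set) {
    for (s in set) if (max(abs(m - s)) < tol) return(TRUE)
    FALSE
  }
  while (length(frontier) > 0) {
    nxt <- list()
    for (f in frontier) {
      if (!is_member(f, ops)) {
        ops <- c(ops, list(f))
        for (o in ops) {
          p1 <- f %*% o
          p2 <- o %*% f
          if (!is_member(p1, ops)) nxt <- c(nxt, list(p1))
          if (!is_member(p2, ops)) nxt <- c(nxt, list(p2))
        }
      }
    }
    frontier <- nxt
    if (length(ops) > 60) stop("closure exceeded order 60; generators inconsistent")
  }
  if (length(ops) != 60) {
    stop(sprintf("closure produced %d operators, expected 60", length(ops)))
  }
  cls <- lapply(ops, classify_operator)
  fold <- vapply(cls, `[[`, character(1), "fold")
  axis <- t(vapply(cls, `[[`, numeric(3), "axis"))
  # canonical deterministic order: identity, then 2-folds, 3-folds, 5-folds,
  # sorted within class by axis then angle
  ang <- vapply(cls, `[[`, numeric(1), "angle_deg")
  key <- order(match(fold, c("identity", "2-fold", "3-fold", "5-fold")),
               round(axis[, 3], 6), round(axis[, 1], 6), round(axis[, 2], 6),
               ang)
  structure(list(operators = ops[key], fold = fold[key], axis = axis[key, , drop = FALSE],
                 orientation_tag = orientation_tag),
            class = "icosa_group")
}

#' @export
print.icosa_group <- function(x, ...) {
  cat(sprintf("Icosahedral rotation group (order %d, setting '%s')\n",
              length(x$operators), x$orientation_tag))
  print(table(x$fold))
  invisible(x)
}

#' Export group operators as a JSON table
#'
#' @param group an `icosa_group`.
#' @param path optional file path; if `NULL` the JSON string is returned.
#' @return JSON string (invisibly if written to file).
#' @export
export_group_json <- function(group, path = NULL) {
  rows <- lapply(seq_along(group$operators), function(i) {
    list(index = i - 1L,
         matrix = as.numeric(t(group$operators[[i]])),
         fold = group$fold[i],
         axis = as.numeric(group$axis[i, ]))
  })
  js <- jsonlite::toJSON(rows, auto_unbox = TRUE, digits = NA)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

#' Export group operators as REMARK 350 BIOMT text
#'
#' Produces the standard `REMARK 350   BIOMT` block (identity translation)
#' describing the biological assembly generated by the group.
#'
#' @param group an `icosa_group`.
#' @return character vector of REMARK lines.
#' @export
export_biomt <- function(group) {
  out <- character(0)
  for (i in seq_along(group$operators)) {
    m <- group$operators[[i]]
    for (r in 1:3) {
      out <- c(out, sprintf("REMARK 350   BIOMT%d %3d%10.6f%10.6f%10.6f%15.5f",
                            r, i, m[r, 1], m[r, 2], m[r, 3], 0))
    }
  }
  out
}

#' Assemble a full capsid from an asymmetric unit
#'
#' Applies every operator of the icosahedral rotation group to every chain of
#' the asymmetric unit. A T=3 asymmetric unit (3 chains) yields 180 subunits;
#' a single chain yields a T=1 shell of 60. Subunit labels combine the
#' quasi-equivalent class letter (A, B, C ... in chain order) with the 1-based
#' operator index, so "A1" is the untransformed copy of the first chain.
#'
#' @param au an `asym_unit` (see [read_structure()]), coordinates in the
#'   group's standard frame with the capsid center at the origin.
#' @param group an `icosa_group` from [generate_group()].
#' @return a `capsid_assembly`: list with `subunits` (list of `capsid_subunit`),
#'   `generator_map` (data.frame label/chain/class/op_index), `t_number`
#'   estimate (`n_chains`), and the `group`.
#' @export
assemble_capsid <- function(au, group) {
  stopifnot(inherits(au, "asym_unit"))
  if (length(au$subunits) == 0) stop("asymmetric unit has no subunits")
  n_ops <- length(group$operators)
  subunits <- vector("list", length(au$subunits) * n_ops)
  map <- vector("list", length(subunits))
  idx <- 0L
  for (ci in seq_along(au$subunits)) {
    ch <- au$subunits[[ci]]
    letter <- LETTERS[ci]
    xyz <- as.matrix(ch$atoms[, c("x", "y", "z")])
    for (k in seq_len(n_ops)) {
      idx <- idx + 1L
      new_xyz <- xyz %*% t(group$operators[[k]])
      at <- ch$atoms
      at$x <- new_xyz[, 1]; at$y <- new_xyz[, 2]; at$z <- new_xyz[, 3]
      label <- sprintf("%s%d", letter, k)
      subunits[[idx]] <- new_subunit(label = label, source_chain = ch$source_chain,
                                     atoms = at)
      map[[idx]] <- data.frame(label = label, chain = ch$source_chain,
                               class = letter, op_index = k,
                               stringsAsFactors = FALSE)
    }
  }
  gm <- do.call(rbind, map)
  structure(list(subunits = stats::setNames(subunits, gm$label),
                 generator_map = gm,
                 n_chains = length(au$subunits),
                 group = group,
                 virus_id = au$virus_id),
            class = "capsid_assembly")
}

#' @export
print.capsid_assembly <- function(x, ...) {
  cat(sprintf("Capsid assembly '%s': %d subunits (%d chains x %d operators)\n",
              x$virus_id %||% "?", length(x$subunits), x$n_chains,
              length(x$group$operators)))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Symmetry operator relating two subunits of an assembly
#'
#' Returns the group element `R_j R_i^-1` carrying subunit `label_i`'s
#' generating frame onto subunit `label_j`'s, classified by fold. For two
#' subunits of the same quasi-equivalent class this operator maps one subunit
#' exactly onto the other.
#'
#' @param assembly a `capsid_assembly`.
#' @param label_i,label_j subunit labels (e.g. `"A1"`, `"B5"`).
#' @return as [classify_operator()], plus the `matrix` itself.
#' @export
relative_operator <- function(assembly, label_i, label_j) {
  gm <- assembly$generator_map
  ki <- gm$op_index[match(label_i, gm$label)]
  kj <- gm$op_index[match(label_j, gm$label)]
  if (is.na(ki)) stop(sprintf("unknown subunit label '%s'", label_i))
  if (is.na(kj)) stop(sprintf("unknown subunit label '%s'", label_j))
  m <- assembly$group$operators[[kj]] %*% t(assembly$group$operators[[ki]])
  out <- classify_operator(m)
  out$matrix <- m
  out
}
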