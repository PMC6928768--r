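#' Construct a capsid subunit
#'
#' A subunit is a single protein chain: a data.frame of atoms plus a label.
#' Atom columns: `serial`, `name`, `element`, `x`, `y`, `z`, `occ`,
#' `is_heavy`, `resno`, `ins`, `resid`.
#'
#' @param label subunit label (e.g. `"A2"`); for an asymmetric-unit chain the
#'   chain identifier.
#' @param source_chain chain identifier in the source structure.
#' @param atoms atom data.frame (see Details).
#' @return object of class `capsid_subunit`.
#' @keywords internal
new_subunit <- function(label, source_chain, atoms) {
  need <- c("serial", "name", "element", "x", "y", "z", "occ", "is_heavy",
            "resno", "ins", "resid")
  miss <- setdiff(need, names(atoms))
  if (length(miss)) stop("atom table missing columns: ", paste(miss, collapse = ", "))
  if (!all(is.finite(atoms$x)) || !all(is.finite(atoms$y)) || !all(is.finite(atoms$z))) {
    stop("non-finite atom coordinates")
  }
  structure(list(label = label, source_chain = source_chain,
                 atoms = atoms[, need]),
            class = "capsid_subunit")
}

#' Construct an asymmetric unit from subunits
#' @param subunits list of `capsid_subunit`.
#' @param virus_id identifier string.
#' @return object of class `asym_unit`.
#' @export
new_asym_unit <- function(subunits, virus_id = "virus") {
  if (length(subunits) == 0) stop("asymmetric unit must contain at least one subunit")
  names(subunits) <- vapply(subunits, `[[`, "", "label")
  structure(list(virus_id = virus_id, subunits = subunits), class = "asym_unit")
}

#' @export
print.asym_unit <- function(x, ...) {
  cat(sprintf("Asymmetric unit '%s': %d chain(s) [%s]\n", x$virus_id,
              length(x$subunits),
              paste(vapply(x$subunits, `[[`, "", "label"), collapse = ", ")))
  invisible(x)
}

hydrogen_name <- function(element) toupper(trimws(element)) %in% c("H", "D")

#' Read a capsid structure (asymmetric unit) from a PDB file
#'
#' Parsing is done with \pkg{bio3d}. Hydrogens are retained but flagged
#' non-heavy (downstream distance/SASA computations use heavy atoms only);
#' when alternate locations are present only the highest-occupancy conformer
#' of each atom is kept; author residue numbering and insertion codes are
#' preserved. If the file carries per-subunit segment identifiers (the dialect
#' written by [write_structure()] for assemblies with more than 62 chains),
#' subunits are split on `segid`, otherwise on the chain identifier.
#'
#' The capsid center is assumed to be at the origin of the input frame (the
#' icosahedral convention of curated capsid structures); set
#' `recenter = TRUE` to translate the centroid of the selection to the origin
#' instead.
#'
#' @param path PDB file path.
#' @param chain_selection optional character vector of chains (or segids) to
#'   keep.
#' @param virus_id identifier stored on the result (default: file base name).
#' @param recenter logical; translate centroid to origin.
#' @return an `asym_unit` with one `capsid_subunit` per selected chain.
#' @export
read_structure <- function(path, chain_selection = NULL, virus_id = NULL,
                           recenter = FALSE) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  pdb <- tryCatch(bio3d::read.pdb(path, verbose = FALSE, multi = FALSE),
                  error = function(e) stop(sprintf("cannot parse PDB '%s': %s",
                                                   path, conditionMessage(e))))
  at <- pdb$atom[pdb$atom$type %in% c("ATOM", "HETATM"), , drop = FALSE]
  if (nrow(at) == 0) stop(sprintf("no atoms in '%s'", path))
  seg <- if (!is.null(at$segid)) trimws(ifelse(is.na(at$segid), "", at$segid)) else
    rep("", nrow(at))
  unit_id <- ifelse(nzchar(seg), seg, as.character(at$chain))
  if (!is.null(chain_selection)) {
    keep <- unit_id %in% chain_selection
    if (!any(keep)) {
      stop(sprintf("no chains matching selection [%s] in '%s'",
                   paste(chain_selection, collapse = ","), path))
    }
    at <- at[keep, , drop = FALSE]
    unit_id <- unit_id[keep]
  }
  # alternate locations: keep the highest-occupancy conformer per atom site
  alt <- ifelse(is.na(at$alt), "", at$alt)
  if (any(nzchar(alt))) {
    occ <- ifelse(is.na(at$o), 1, at$o)
    site <- paste(unit_id, at$resno, ifelse(is.na(at$insert), "", at$insert),
                  at$resid, at$elety, sep = "|")
    ord <- order(site, -occ)
    at <- at[ord, , drop = FALSE][!duplicated(site[ord]), , drop = FALSE]
    unit_id <- unit_id[ord][!duplicated(site[ord])]
    reord <- order(at$eleno)
    at <- at[reord, , drop = FALSE]
    unit_id <- unit_id[reord]
  }
  if (recenter) {
    ctr <- c(mean(at$x), mean(at$y), mean(at$z))
    at$x <- at$x - ctr[1]; at$y <- at$y - ctr[2]; at$z <- at$z - ctr[3]
  }
  elem <- at$elesy
  if (is.null(elem) || all(is.na(elem))) elem <- rep(NA_character_, nrow(at))
  # fall back to first letter of the atom name when the element column is blank
  elem <- ifelse(is.na(elem) | !nzchar(trimws(elem)),
                 sub("^[0-9]*([A-Za-z]).*", "\\1", at$elety), trimws(elem))
  elem <- toupper(elem)
  subunits <- lapply(unique(unit_id), function(u) {
    rows <- unit_id == u
    a <- at[rows, , drop = FALSE]
    atoms <- data.frame(serial = a$eleno, name = a$elety, element = elem[rows],
                        x = a$x, y = a$y, z = a$z,
                        occ = ifelse(is.na(a$o), 1, a$o),
                        is_heavy = !hydrogen_name(elem[rows]),
                        resno = a$resno,
                        ins = ifelse(is.na(a$insert), "", a$insert),
                        resid = a$resid, stringsAsFactors = FALSE)
    src <- as.character(a$chain[1])
    new_subunit(label = u, source_chain = if (is.na(src)) u else src, atoms = atoms)
  })
  new_asym_unit(subunits, virus_id = virus_id %||% sub("\\.[^.]*$", "", basename(path)))
}

#' Write subunits to a PDB file
#'
#' Writes fixed-column ATOM records. Chain identifiers are a single character
#' (the quasi-equivalent class letter); the full subunit label (e.g. `"B17"`)
#' is written into the 4-character segment-identifier field (columns 73-76),
#' which is how assemblies with more than 62 subunits stay in one valid file
#' — [read_structure()] splits subunits on that field. Files that would
#' exceed the 99,999 atom-serial limit are written as successive MODEL blocks
#' with serials restarting in each block.
#'
#' @param subunits a list of `capsid_subunit`, a `capsid_assembly`, or an
#'   `asym_unit`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(subunits, path) {
  if (inherits(subunits, "capsid_assembly") || inherits(subunits, "asym_unit")) {
    subunits <- subunits$subunits
  }
  if (inherits(subunits, "capsid_subunit")) subunits <- list(subunits)
  if (length(subunits) == 0) stop("refusing to write an empty structure")
  natoms <- sum(vapply(subunits, function(s) nrow(s$atoms), integer(1)))
  multi_model <- natoms > 99999L
  con <- file(path, "w")
  on.exit(close(con))
  serial <- 0L
  model <- 0L
  open_model <- FALSE
  for (s in subunits) {
    a <- s$atoms
    if (!all(is.finite(c(a$x, a$y, a$z)))) stop("non-finite coordinates")
    if (multi_model && (serial + nrow(a) > 99999L || !open_model)) {
      if (open_model) writeLines("ENDMDL", con)
      model <- model + 1L
      writeLines(sprintf("MODEL     %4d", model), con)
      open_model <- TRUE
      serial <- 0L
    }
    chain1 <- substr(s$label, 1, 1)
    segid <- sprintf("%-4s", substr(s$label, 1, 4))
    nm <- ifelse(nchar(a$name) < 4, sprintf(" %-3s", a$name), a$name)
    lines <- sprintf(
      "ATOM  %5d %4s %-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f      %4s%2s",
      (serial + seq_len(nrow(a))) %% 100000L, nm, a$resid, chain1,
      a$resno, ifelse(nzchar(a$ins), a$ins, " "),
      a$x, a$y, a$z, a$occ, 0, segid, sprintf("%2s", a$element))
    writeLines(lines, con)
    serial <- serial + nrow(a)
    if (!multi_model) writeLines("TER", con)
  }
  if (open_model) writeLines("ENDMDL", con)
  writeLines("END", con)
  invisible(path)
}

#' Read a multiple sequence alignment
#'
#' FASTA or Clustal, via \pkg{Biostrings}. Sequences are upper-cased and the
#' gap characters `.` and `~` are unified to `-`.
#'
#' @param path alignment file.
#' @param format `"fasta"` or `"clustal"`.
#' @return an `alignment_set`: list with `sequences` (named character vector
#'   of aligned rows) and `n_columns`.
#' @export
read_alignment <- function(path, format = c("fasta", "clustal")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  aln <- Biostrings::readAAMultipleAlignment(path, format = format)
  seqs <- as.character(Biostrings::unmasked(aln))
  new_alignment_set(seqs)
}

#' Construct an alignment set from aligned strings
#'
#' @param sequences named character vector of equal-length aligned sequences.
#' @return an `alignment_set`.
#' @export
new_alignment_set <- function(sequences) {
  if (length(sequences) == 0) stop("empty alignment")
  sequences <- toupper(sequences)
  sequences <- gsub("[.~]", "-", sequences)
  lens <- nchar(sequences)
  if (length(unique(lens)) != 1) {
    bad <- names(sequences)[which(lens != lens[1])[1]] %||% which(lens != lens[1])[1]
    stop(sprintf("ragged alignment: sequence '%s' has length %d, expected %d",
                 bad, lens[lens != lens[1]][1], lens[1]))
  }
  if (is.null(names(sequences))) names(sequences) <- paste0("seq", seq_along(sequences))
  structure(list(sequences = sequences, n_columns = unname(lens[1])),
            class = "alignment_set")
}

#' Read umbrella-sampling window series
#'
#' The metadata table is TSV with columns `window_id`, `center_nm`,
#' `spring_k_kJ_mol_nm2` (and optionally `file`); each window's reaction
#' coordinate samples live in `<series_dir>/window_<id>.xvg` (or the `file`
#' column) as a two-column (time, xi) plain-text table. Lines starting with
#' `#` or `@` are ignored, covering the common pull-code output dialect.
#'
#' @param metadata_path TSV metadata file.
#' @param series_dir directory holding the per-window series files.
#' @param temperature simulation temperature in K attached to each window.
#' @return list of `window_series`: each has `window_id`, `center` (nm),
#'   `spring_k` (kJ/mol/nm^2), `samples` (nm), `temperature` (K).
#' @export
read_window_series <- function(metadata_path, series_dir, temperature = 300) {
  if (!file.exists(metadata_path)) stop(sprintf("file not found: %s", metadata_path))
  md <- utils::read.delim(metadata_path, stringsAsFactors = FALSE)
  need <- c("window_id", "center_nm", "spring_k_kJ_mol_nm2")
  miss <- setdiff(need, names(md))
  if (length(miss)) stop("metadata missing column(s): ", paste(miss, collapse = ", "))
  if (any(md$spring_k_kJ_mol_nm2 <= 0)) {
    stop("spring_k must be > 0 for all windows (found non-positive values)")
  }
  files <- if ("file" %in% names(md)) file.path(series_dir, md$file) else
    file.path(series_dir, sprintf("window_%d.xvg", md$window_id))
  missing_f <- !file.exists(files)
  if (any(missing_f)) {
    stop("missing series file(s) for window id(s): ",
         paste(md$window_id[missing_f], collapse = ", "))
  }
  lapply(seq_len(nrow(md)), function(i) {
    ln <- readLines(files[i])
    ln <- ln[!grepl("^\\s*[#@]", ln) & nzchar(trimws(ln))]
    if (length(ln) == 0) stop(sprintf("window %d: series file has no samples",
                                      md$window_id[i]))
    vals <- utils::read.table(text = ln)
    new_window_series(window_id = md$window_id[i], center = md$center_nm[i],
                      spring_k = md$spring_k_kJ_mol_nm2[i],
                      samples = vals[[ncol(vals)]], temperature = temperature)
  })
}

#' Construct an umbrella window series
#' @param window_id integer id.
#' @param center bias center, nm.
#' @param spring_k harmonic spring constant, kJ/mol/nm^2.
#' @param samples reaction-coordinate samples, nm.
#' @param temperature K.
#' @return a `window_series`.
#' @export
new_window_series <- function(window_id, center, spring_k, samples,
                              temperature = 300) {
  if (length(samples) == 0) stop("window series must contain samples")
  if (spring_k <= 0) stop("spring_k must be > 0")
  if (temperature <= 0) stop("temperature must be > 0")
  structure(list(window_id = as.integer(window_id), center = center,
                 spring_k = spring_k, samples = as.numeric(samples),
                 temperature = temperature),
            class = "window_series")
}

#' Write window series plus metadata to disk
#'
#' Inverse of [read_window_series()]; used by the synthetic generators so the
#' text I/O path is exercised end-to-end.
#'
#' @param windows list of `window_series`.
#' @param dir output directory (created if absent).
#' @return the metadata file path, invisibly.
#' @export
write_window_series <- function(windows, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  md <- data.frame(window_id = vapply(windows, `[[`, integer(1), "window_id"),
                   center_nm = vapply(windows, `[[`, numeric(1), "center"),
                   spring_k_kJ_mol_nm2 = vapply(windows, `[[`, numeric(1), "spring_k"))
  meta <- file.path(dir, "windows.tsv")
  utils::write.table(md, meta, sep = "\t", row.names = FALSE, quote = FALSE)
  for (w in windows) {
    f <- file.path(dir, sprintf("window_%d.xvg", w$window_id))
    writeLines(c("# synthetic umbrella window",
                 sprintf("%g\t%.8f", seq_along(w$samples), w$samples)), f)
  }
  invisible(meta)
}
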