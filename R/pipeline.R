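#' Run the full conservation-based hot-spot prediction pipeline
#'
#' For each family member: assemble the capsid with the icosahedral group,
#' find every interface of the asymmetric-unit subunits, and build the
#' angular capsid map of the interface residues. Across members: find the
#' strictly conserved alignment columns, align the maps with the angular
#' overlap threshold, and intersect the three sets. Hot spots are reported in
#' reference-member numbering with the symmetry fold of the interfaces they
#' sit in.
#'
#' @param members named list; each element has `au` (an `asym_unit`) and
#'   `sequence` (aligned string) — the structure returned by
#'   [make_toy_family()]`$members`, or assembled by hand from
#'   [read_structure()] / [read_alignment()].
#' @param criterion a [contact_criterion()].
#' @param angle_threshold degrees (default 3).
#' @param reference reference member id (default first).
#' @param chain_class quasi-equivalent class whose residue numbering is
#'   reported (default `"A"`).
#' @param offsets named integer vector: first author residue number per
#'   member (default 1).
#' @param point_mode representative-point mode, see [residue_point()].
#' @param require_all_members,quorum see [align_maps()].
#' @return a `hotspot_result` (see [predict_hotspots()]), with the capsid
#'   maps and interface pair lists attached as attributes `maps` and `pairs`.
#' @export
run_prediction <- function(members, criterion = contact_criterion(),
                           angle_threshold = 3, reference = NULL,
                           chain_class = "A", offsets = NULL,
                           point_mode = "sidechain",
                           require_all_members = TRUE, quorum = 0.5) {
  if (length(members) < 2) {
    stop(paste("at least two family members are required: a single structure",
               "cannot show quaternary-position conservation"))
  }
  if (is.null(names(members))) {
    names(members) <- vapply(members, function(m) m$au$virus_id, "")
  }
  reference <- reference %||% names(members)[1]
  grp <- generate_group()
  interface_sets <- list()
  maps <- list()
  pair_list <- list()
  for (v in names(members)) {
    au <- members[[v]]$au
    asm <- assemble_capsid(au, grp)
    au_labels <- sprintf("%s1", LETTERS[seq_along(au$subunits)])
    pairs <- find_interfaces(asm, criterion, focus = au_labels)
    sets <- lapply(stats::setNames(nm = LETTERS[seq_along(au$subunits)]),
                   function(cl) interface_residue_union(pairs, cl))
    interface_sets[[v]] <- sets
    maps[[v]] <- build_capsidmap(au, sets, point_mode = point_mode)
    pair_list[[v]] <- pairs
  }
  aln <- new_alignment_set(vapply(members, `[[`, "", "sequence"))
  corr <- msa_residue_map(aln, offsets)
  seq_cons <- conserved_columns(aln, offsets)
  space <- align_maps(maps, corr, angle_threshold = angle_threshold,
                      require_all_members = require_all_members,
                      quorum = quorum, reference = reference)
  space_ref <- space[space$chain == chain_class, , drop = FALSE]
  fold_ann <- export_interface_table(pair_list[[reference]], reference)
  fold_ann <- fold_ann[substr(fold_ann$subunit, 1, 1) == chain_class,
                       c("resno", "fold")]
  res <- predict_hotspots(
    interface_sets = lapply(interface_sets, `[[`, chain_class),
    seq_conserved = seq_cons$residue_numbers[[reference]],
    space_conserved = space_ref,
    reference = reference,
    fold_annotation = fold_ann)
  attr(res, "maps") <- maps
  attr(res, "pairs") <- pair_list
  res
}

#' Write a hot-spot prediction report
#'
#' Emits a TSV of the hot spots and a JSON report listing the three sets and
#' the intersection. Output is deterministic (no timestamps).
#'
#' @param result a `hotspot_result`.
#' @param dir output directory (created if needed).
#' @return paths of the written files, invisibly.
#' @export
write_hotspot_report <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tsv <- file.path(dir, "hot_spots.tsv")
  utils::write.table(result$hot_spots, tsv, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  js <- file.path(dir, "hot_spots.json")
  jsonlite::write_json(
    list(reference = result$reference,
         interface_sets = result$interface_sets,
         sequence_conserved = result$sequence_conserved,
         space_conserved = result$space_conserved,
         hot_spots = result$hot_spots),
    js, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(tsv = tsv, json = js))
}

#' Run the umbrella-sampling analysis for one or more variants
#'
#' For each variant: histogram the window series, solve WHAM, build the PMF
#' and extract the binding free energy, optionally with bootstrap errors;
#' then difference every variant against the designated wild type.
#'
#' @param variants named list: variant id -> list of `window_series` (e.g.
#'   from [read_window_series()] or [sample_umbrella()]).
#' @param wild_type name of the reference variant (default first).
#' @param temperature K.
#' @param bin_width nm.
#' @param n_boot bootstrap replicates (0 to skip error estimation).
#' @param seed bootstrap seed.
#' @param tol,max_iter WHAM numerics.
#' @return list with `profiles` (named `pmf_profile`s), `energies` (named
#'   `binding_energy`s) and `table` (data.frame variant/dg/dg_err/ddg/ddg_err,
#'   the usual free-energy bookkeeping layout).
#' @export
run_pmf_analysis <- function(variants, wild_type = names(variants)[1],
                             temperature = 300, bin_width = 0.05,
                             n_boot = 0, seed = 1, tol = 1e-8,
                             max_iter = 100000L) {
  if (!wild_type %in% names(variants)) stop("unknown wild-type variant id")
  profiles <- list(); energies <- list(); conv <- list()
  for (v in names(variants)) {
    ws <- variants[[v]]
    biases <- lapply(ws, function(w) bias_potential(w$center, w$spring_k))
    hist <- build_histograms(ws, bin_width)
    sol <- solve_wham(hist, biases, temperature, tol = tol, max_iter = max_iter)
    pmf <- pmf_from_solution(sol)
    err <- NA_real_
    if (n_boot >= 2) {
      err <- bootstrap_dg(ws, biases, temperature, n_boot = n_boot,
                          seed = seed, bin_width = bin_width)$dg_err
    }
    profiles[[v]] <- pmf
    energies[[v]] <- binding_dg(pmf, dg_err = err, variant_id = v)
    conv[[v]] <- list(converged = sol$converged, iterations = sol$iterations)
  }
  wt <- energies[[wild_type]]
  tab <- do.call(rbind, lapply(names(energies), function(v) {
    dd <- delta_delta_g(energies[[v]], wt)
    data.frame(variant = v, dg = energies[[v]]$dg, dg_err = energies[[v]]$dg_err,
               ddg = dd$ddg, ddg_err = dd$ddg_err, stringsAsFactors = FALSE)
  }))
  list(profiles = profiles, energies = energies, table = tab,
       convergence = conv)
}
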