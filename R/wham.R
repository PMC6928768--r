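#' Physical constants and unit conversions
#'
#' Boltzmann constant in kcal/(mol K) and the kJ-to-kcal factor used for all
#' internal energy bookkeeping (spring constants arrive in kJ/mol/nm^2, free
#' energies are reported in kcal/mol).
#' @name units
#' @keywords internal
NULL

KB_KCAL <- 0.0019872   # kcal mol^-1 K^-1
KJ_PER_KCAL <- 4.184

#' Harmonic bias potential of an umbrella window
#'
#' `w(xi) = 1/2 k (xi - center)^2`.
#'
#' @param center bias center, nm.
#' @param spring_k spring constant, kJ/mol/nm^2.
#' @return a `bias_potential` with an evaluation function `energy(xi)`
#'   returning kcal/mol.
#' @export
bias_potential <- function(center, spring_k) {
  if (spring_k <= 0) stop("spring_k must be > 0")
  k_kcal <- spring_k / KJ_PER_KCAL
  structure(list(center = center, spring_k = spring_k,
                 energy = function(xi) 0.5 * k_kcal * (xi - center)^2),
            class = "bias_potential")
}

#' Histogram umbrella-window samples on a common grid
#'
#' Bins are left-closed, right-open (`[edge_b, edge_{b+1})`); a sample
#' falling exactly on an edge is assigned to the bin starting there. The top
#' edge is extended by one bin so the maximum sample is always counted, which
#' makes the binning conserve samples exactly.
#'
#' @param windows list of `window_series`.
#' @param bin_width nm (default 0.05).
#' @return a `histogram_set`: `bin_edges`, `bin_centers` (nm), `counts`
#'   (windows x bins integer matrix), `totals` (per-window sample counts),
#'   `temperature`.
#' @export
build_histograms <- function(windows, bin_width = 0.05) {
  if (length(windows) == 0) stop("no windows")
  if (bin_width <= 0) stop("bin width must be > 0")
  temps <- unique(vapply(windows, `[[`, numeric(1), "temperature"))
  if (length(temps) != 1) stop("windows have differing temperatures")
  all_s <- unlist(lapply(windows, `[[`, "samples"))
  lo <- floor(min(all_s) / bin_width) * bin_width
  nb <- floor((max(all_s) - lo) / bin_width) + 1L
  edges <- lo + bin_width * (0:nb)
  counts <- t(vapply(windows, function(w) {
    idx <- floor((w$samples - lo) / bin_width) + 1L
    tabulate(idx, nbins = nb)
  }, integer(nb)))
  structure(list(bin_edges = edges, bin_centers = edges[-length(edges)] + bin_width / 2,
                 counts = counts,
                 totals = vapply(windows, function(w) length(w$samples), integer(1)),
                 temperature = temps),
            class = "histogram_set")
}

logsumexp_rows <- function(m) {
  mx <- apply(m, 1, max)
  mx + log(rowSums(exp(m - mx)))
}

#' Solve the WHAM equations
#'
#' Self-consistent iteration of the standard coupled equations
#' \deqn{P(b) = \frac{\sum_j n_j(b)}{\sum_j N_j \exp[(F_j - w_j(b))/k_BT]},
#'   \qquad F_j = -k_BT \ln \sum_b P(b) e^{-w_j(b)/k_BT},}
#' in log space (log-sum-exp throughout) with the gauge `F_1 = 0`, until
#' `max_j |dF_j| < tol`. Bins with zero total count are excluded.
#'
#' @param hist a `histogram_set`.
#' @param biases list of `bias_potential`, aligned 1:1 with the histogram's
#'   windows.
#' @param temperature K (default: histogram temperature).
#' @param tol convergence tolerance on window offsets, kcal/mol.
#' @param max_iter iteration cap.
#' @param f_init optional starting window offsets (kcal/mol); the converged
#'   solution does not depend on them.
#' @return a `wham_solution`: `xi` (occupied bin centers, nm),
#'   `unbiased_prob` (normalized over occupied bins), `window_offsets`
#'   (kcal/mol, first fixed at 0), `converged`, `iterations`, `temperature`.
#' @export
solve_wham <- function(hist, biases, temperature = NULL, tol = 1e-8,
                       max_iter = 100000L, f_init = NULL) {
  nw <- nrow(hist$counts)
  if (length(biases) != nw) stop("need one bias per window")
  temperature <- temperature %||% hist$temperature
  kbt <- KB_KCAL * temperature
  occ <- colSums(hist$counts) > 0
  check_window_overlap(hist, occ)
  xb <- hist$bin_centers[occ]
  n_b <- colSums(hist$counts)[occ]
  N_j <- hist$totals
  # w[j, b] in kcal/mol
  w <- t(vapply(biases, function(bp) bp$energy(xb), numeric(length(xb))))
  f <- f_init %||% rep(0, nw)
  if (length(f) != nw) stop("f_init must have one offset per window")
  logN <- log(N_j)
  log_nb <- log(n_b)
  it <- 0L
  converged <- FALSE
  while (it < max_iter) {
    it <- it + 1L
    # A[j, b] = log N_j + (F_j - w_jb)/kbt
    A <- sweep(-w / kbt, 1, f / kbt + logN, "+")
    mx <- apply(A, 2, max)
    log_denom <- mx + log(colSums(exp(sweep(A, 2, mx))))
    logP <- log_nb - log_denom
    f_new <- -kbt * logsumexp_rows(sweep(-w / kbt, 2, logP, "+"))
    f_new <- f_new - f_new[1]
    delta <- max(abs(f_new - f))
    f <- f_new
    if (delta < tol) { converged <- TRUE; break }
  }
  logP <- logP - max(logP)
  P <- exp(logP); P <- P / sum(P)
  structure(list(xi = xb, unbiased_prob = P, window_offsets = f,
                 bin_counts = n_b, converged = converged, iterations = it,
                 temperature = temperature),
            class = "wham_solution")
}

# flag adjacent occupied windows with no mutual histogram support
check_window_overlap <- function(hist, occ) {
  nw <- nrow(hist$counts)
  if (nw < 2) return(invisible(TRUE))
  occm <- hist$counts[, occ, drop = FALSE] > 0
  ord <- order(vapply(seq_len(nw), function(j) {
    stats::weighted.mean(hist$bin_centers[occ], hist$counts[j, occ])
  }, numeric(1)))
  for (k in seq_len(nw - 1)) {
    a <- ord[k]; b <- ord[k + 1]
    if (!any(occm[a, ] & occm[b, ])) {
      warning(sprintf("windows %d and %d share no occupied bins", a, b))
      stop(sprintf(paste0("disconnected sampling: adjacent windows %d and %d ",
                          "have no overlapping support"), a, b))
    }
  }
  invisible(TRUE)
}

#' Potential of mean force from a WHAM solution
#'
#' `g(xi) = -k_BT ln P(xi)`, zero-referenced to the mean over the last
#' occupied 5% of the sampled reaction-coordinate range — the large-separation
#' plateau where the subunits no longer interact.
#'
#' @param sol a `wham_solution`.
#' @param temperature K (default: solution temperature).
#' @param reference_frac fraction of the xi range used as the zero plateau.
#' @param force proceed even if the solution did not converge.
#' @return a `pmf_profile`: `xi` (nm), `g` (kcal/mol), `reference_xi`,
#'   `temperature`.
#' @export
pmf_from_solution <- function(sol, temperature = NULL, reference_frac = 0.05,
                              force = FALSE) {
  if (!sol$converged && !force) {
    stop("WHAM solution did not converge; rerun with more iterations or force = TRUE")
  }
  temperature <- temperature %||% sol$temperature
  kbt <- KB_KCAL * temperature
  g <- -kbt * log(sol$unbiased_prob)
  span <- diff(range(sol$xi))
  ref_lo <- max(sol$xi) - reference_frac * span
  ref <- sol$xi >= ref_lo
  # starved edge bins carry large noise; keep only reasonably filled bins in
  # the plateau average (but never none)
  if (!is.null(sol$bin_counts)) {
    filled <- sol$bin_counts >= 0.2 * stats::median(sol$bin_counts)
    if (any(ref & filled)) ref <- ref & filled
  }
  g <- g - mean(g[ref])
  structure(list(xi = sol$xi, g = g, reference_xi = mean(sol$xi[ref]),
                 reference_region = range(sol$xi[ref]),
                 temperature = temperature),
            class = "pmf_profile")
}

#' Construct a PMF profile directly from values
#'
#' Convenience constructor for already-zeroed profiles (e.g. published curves
#' re-used for difference bookkeeping).
#'
#' @param xi reaction coordinate, nm.
#' @param g free energy, kcal/mol, zero at large separation.
#' @param temperature K.
#' @return a `pmf_profile`.
#' @export
pmf_profile <- function(xi, g, temperature = 300) {
  stopifnot(length(xi) == length(g), all(is.finite(g)))
  ref <- xi >= max(xi) - 0.05 * diff(range(xi))
  structure(list(xi = xi, g = g, reference_xi = mean(xi[ref]),
                 reference_region = range(xi[ref]), temperature = temperature),
            class = "pmf_profile")
}

#' Binding free energy from a PMF profile
#'
#' The binding free energy is the global minimum of the zero-referenced PMF;
#' ties break toward smaller separation. If the minimum falls in the
#' large-separation reference region (or is non-negative) there is no stable
#' complex: `dg = 0` with `no_binding = TRUE`.
#'
#' @param pmf a `pmf_profile`.
#' @param dg_err optional bootstrap error to attach (kcal/mol).
#' @param variant_id label.
#' @return a `binding_energy`: `dg`, `dg_err`, `xi_min`, `no_binding`,
#'   `variant_id`, `temperature`.
#' @export
binding_dg <- function(pmf, dg_err = NA_real_, variant_id = "") {
  k <- which.min(pmf$g)  # which.min takes the first (smallest xi) on ties
  no_bind <- pmf$g[k] >= 0 || pmf$xi[k] >= pmf$reference_region[1]
  structure(list(dg = if (no_bind) 0 else pmf$g[k],
                 dg_err = dg_err,
                 xi_min = pmf$xi[k],
                 no_binding = no_bind,
                 variant_id = variant_id,
                 temperature = pmf$temperature),
            class = "binding_energy")
}

#' Mutation-induced change in binding free energy
#'
#' `ddG = dG(mutant) - dG(wild type)`, with errors propagated in quadrature.
#' A destabilizing mutation (weaker binding) gives a positive value.
#'
#' @param mutant,wild_type `binding_energy` objects sharing temperature and
#'   reference convention.
#' @return list with `ddg` and `ddg_err` (kcal/mol).
#' @export
delta_delta_g <- function(mutant, wild_type) {
  if (!isTRUE(all.equal(mutant$temperature, wild_type$temperature))) {
    stop("mutant and wild type were analysed at different temperatures")
  }
  list(ddg = mutant$dg - wild_type$dg,
       ddg_err = sqrt(sum(c(mutant$dg_err, wild_type$dg_err)^2, na.rm = FALSE)))
}

#' Bootstrap error of the binding free energy
#'
#' Block bootstrap over each window's samples: contiguous blocks of
#' `block_len` samples are resampled with replacement (block length 1 =
#' ordinary bootstrap, appropriate for uncorrelated samples; raise it to
#' respect autocorrelation in MD series), WHAM is re-solved and the standard
#' deviation of the resulting binding free energies is reported.
#'
#' @param windows list of `window_series`.
#' @param biases list of `bias_potential`.
#' @param temperature K.
#' @param n_boot number of bootstrap replicates (>= 2).
#' @param seed RNG seed (reproducible).
#' @param bin_width nm.
#' @param block_len block length in samples.
#' @param tol,max_iter WHAM numerics for the replicates.
#' @return list with `dg_err` (sd, kcal/mol) and the replicate `dg` values.
#' @export
bootstrap_dg <- function(windows, biases, temperature = 300, n_boot = 20,
                         seed = 1, bin_width = 0.05, block_len = 1,
                         tol = 1e-6, max_iter = 100000L) {
  if (n_boot < 2) stop("n_boot must be >= 2")
  set.seed(seed)
  dgs <- vapply(seq_len(n_boot), function(b) {
    resampled <- lapply(windows, function(w) {
      s <- resample_blocks(w$samples, block_len)
      new_window_series(w$window_id, w$center, w$spring_k, s, w$temperature)
    })
    hist <- build_histograms(resampled, bin_width)
    sol <- solve_wham(hist, biases, temperature, tol = tol, max_iter = max_iter)
    binding_dg(pmf_from_solution(sol, force = TRUE))$dg
  }, numeric(1))
  list(dg_err = stats::sd(dgs), dg_boot = dgs)
}

resample_blocks <- function(x, block_len) {
  n <- length(x)
  if (block_len <= 1) return(x[sample.int(n, n, replace = TRUE)])
  nblk <- ceiling(n / block_len)
  starts <- sample.int(max(1, n - block_len + 1), nblk, replace = TRUE)
  idx <- unlist(lapply(starts, function(s) s:(s + block_len - 1)))
  x[idx[seq_len(n)]]
}

#' Export a PMF profile as TSV
#' @param pmf a `pmf_profile`.
#' @param path output path.
#' @return the data.frame, invisibly.
#' @export
export_pmf <- function(pmf, path) {
  df <- data.frame(xi_nm = pmf$xi, g_kcal_mol = pmf$g)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(df)
}
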