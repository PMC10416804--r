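#' Describe a synthetic single-cell count scenario
#'
#' Stands in for the sequencer: negative-binomial raw counts for a panel of
#' genes across cells of three invasion phenotypes, with a designated
#' housekeeping panel, phenotype-specific expression blocks (planted log2
#' fold-changes), and a planted fraction of low-depth "failed" cells whose
#' expected counts are scaled down uniformly (a failed library, not
#' biology).
#'
#' Defaults mirror a plate-based SMART-Seq study of spheroid invasion
#' phenotypes: 12 epithelial, 16 escaping and 16 amoeboid cells (44 total),
#' a 22-gene housekeeping panel, and roughly one in five libraries failing.
#'
#' @param n_genes Total number of genes (including the housekeeping panel).
#' @param n_housekeeping Housekeeping panel size.
#' @param cells_per_phenotype Named integer vector (epithelial, escaping,
#'   amoeboid).
#' @param base_mean_log Mean of log-normal baseline gene means.
#' @param base_mean_sdlog SD of log-normal baseline gene means.
#' @param housekeeping_mean Expected raw count of housekeeping genes.
#' @param dispersion NB dispersion (size = 1/dispersion); must be > 0.
#' @param n_de_genes Number of non-housekeeping genes given planted fold
#'   changes per transition block (epithelial->escaping and
#'   escaping->amoeboid).
#' @param log2fc Planted log2 fold-change magnitude for the DE blocks.
#' @param low_quality_fraction Fraction of cells planted as failed.
#' @param depth_scaling Multiplier applied to all expected counts of failed
#'   cells.
#' @param seed Integer seed; fixed seed gives an identical matrix.
#' @return An object of class `count_scenario`.
#' @export
count_scenario <- function(n_genes = 600,
                           n_housekeeping = 22,
                           cells_per_phenotype = c(epithelial = 12,
                                                   escaping = 16,
                                                   amoeboid = 16),
                           base_mean_log = log(30),
                           base_mean_sdlog = 1,
                           housekeeping_mean = 300,
                           dispersion = 0.4,
                           n_de_genes = 80,
                           log2fc = 3,
                           low_quality_fraction = 8 / 44,
                           depth_scaling = 0.01,
                           seed = 1L) {
  if (dispersion <= 0) abort("`dispersion` must be > 0.")
  if (n_housekeeping < 1 || n_housekeeping > n_genes) {
    abort("`n_housekeeping` must be between 1 and `n_genes`.")
  }
  ph <- c("epithelial", "escaping", "amoeboid")
  if (!all(ph %in% names(cells_per_phenotype))) {
    abort("`cells_per_phenotype` must name epithelial, escaping and amoeboid.")
  }
  if (low_quality_fraction < 0 || low_quality_fraction >= 1) {
    abort("`low_quality_fraction` must be in [0, 1).")
  }
  if (depth_scaling < 0) abort("`depth_scaling` must be >= 0.")
  if (2L * n_de_genes > n_genes - n_housekeeping) {
    abort("not enough non-housekeeping genes for the requested DE blocks.")
  }
  structure(
    list(n_genes = as.integer(n_genes),
         n_housekeeping = as.integer(n_housekeeping),
         cells_per_phenotype = cells_per_phenotype[ph],
         base_mean_log = base_mean_log, base_mean_sdlog = base_mean_sdlog,
         housekeeping_mean = housekeeping_mean, dispersion = dispersion,
         n_de_genes = as.integer(n_de_genes), log2fc = log2fc,
         low_quality_fraction = low_quality_fraction,
         depth_scaling = depth_scaling, seed = as.integer(seed)),
    class = "count_scenario"
  )
}

#' Generate a raw count matrix with known phenotype and QC structure
#'
#' Gene means are log-normal; housekeeping genes share a common high mean;
#' two blocks of `n_de_genes` genes get `2^log2fc`-fold planted up-shifts in
#' the escaping+amoeboid and amoeboid-only phenotypes respectively. Counts
#' are NB(mu, size = 1/dispersion). Planted failed cells keep their
#' phenotype but have every expected count multiplied by `depth_scaling`.
#'
#' @param scenario A [count_scenario()].
#' @return A list with `counts` (integer genes x cells matrix with gene and
#'   cell ids), `truth` (tibble: cell_id, phenotype, failed) and
#'   `housekeeping_panel` (character vector of panel gene ids).
#' @export
generate_counts <- function(scenario) {
  stopifnot(inherits(scenario, "count_scenario"))
  with_seed(scenario$seed, {
    ng <- scenario$n_genes
    nhk <- scenario$n_housekeeping
    hk_genes <- sprintf("HK%02d", seq_len(nhk))
    other <- sprintf("G%04d", seq_len(ng - nhk))
    genes <- c(hk_genes, other)
    cpp <- scenario$cells_per_phenotype
    prefixes <- c(epithelial = "E", escaping = "Es", amoeboid = "A")
    phen <- rep(names(cpp), times = cpp)
    cell_ids <- unlist(lapply(names(cpp), function(p) {
      sprintf("%s-%02d", prefixes[[p]], seq_len(cpp[[p]]))
    }), use.names = FALSE)
    n_cells <- length(cell_ids)
    base_mu <- c(rep(scenario$housekeeping_mean, nhk),
                 stats::rlnorm(ng - nhk, scenario$base_mean_log,
                               scenario$base_mean_sdlog))
    mu <- matrix(base_mu, nrow = ng, ncol = n_cells)
    # planted DE blocks on non-housekeeping genes:
    # block 1 up in escaping + amoeboid (tumor-escape programme),
    # block 2 up in amoeboid only (amoeboid-migration programme)
    nde <- scenario$n_de_genes
    fc <- 2^scenario$log2fc
    if (nde > 0) {
      b1 <- nhk + seq_len(nde)
      b2 <- nhk + nde + seq_len(nde)
      mu[b1, phen != "epithelial"] <- mu[b1, phen != "epithelial"] * fc
      mu[b2, phen == "amoeboid"] <- mu[b2, phen == "amoeboid"] * fc
    }
    n_fail <- floor(scenario$low_quality_fraction * n_cells)
    failed <- rep(FALSE, n_cells)
    if (n_fail > 0) {
      failed[sample.int(n_cells, n_fail)] <- TRUE
      mu[, failed] <- mu[, failed] * scenario$depth_scaling
    }
    counts <- matrix(
      rnbinom(ng * n_cells, mu = as.vector(mu), size = 1 / scenario$dispersion),
      nrow = ng, ncol = n_cells, dimnames = list(genes, cell_ids)
    )
    storage.mode(counts) <- "integer"
    list(
      counts = counts,
      truth = tibble(cell_id = cell_ids, phenotype = phen, failed = failed),
      housekeeping_panel = hk_genes
    )
  })
}
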