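#' Default cell types and marker panels for the liver cohort generator
#'
#' Hepatocyte, cholangiocyte and progenitor panels are the classic liver
#' lineage markers used for annotation; the remaining types carry standard
#' lineage markers so the simulated tissue has a realistic mixture of
#' epithelial, endothelial, mesenchymal and immune populations. The LPC type
#' draws elevated means for BOTH epithelial panels plus the progenitor panel,
#' which is the bipotency signal the annotation stage is designed to detect.
#' @noRd
default_cell_types <- function() {
  list(
    hepatocyte   = c("PCK1", "TF", "ALB", "HP"),
    cholangiocyte = c("SOX9", "KRT7", "KRT18", "SOX4"),
    LPC = c("EPCAM", "PCNA", "HNF1A", "CDK1", "CD24", "TACSTD2", "NFKB1"),
    endothelial  = c("PECAM1", "VWF", "CDH5"),
    HSC          = c("ACTA2", "COL1A1", "DCN"),
    macrophage   = c("CD68", "LYZ", "CD163"),
    T_cell       = c("CD3D", "CD3E", "CD2"),
    B_cell       = c("CD79A", "MS4A1")
  )
}

#' Configuration for the single-cell cohort generator
#'
#' Defines a cohort of individuals across liver conditions (FL fetal, HL
#' healthy, CL cirrhotic, TL tumor, TLA tumor-adjacent) with planted cell-type
#' structure: per-individual cluster frequencies follow a logistic-normal
#' model (softmax of Gaussian logits), optionally driven by latent factors so
#' that groups of clusters covary across individuals; a rare bipotent LPC
#' population is planted at a controlled per-individual fraction of the
#' merged epithelial + LPC compartment; counts are negative binomial with
#' per-cell lognormal library sizes.
#'
#' @param n_individuals number of individuals (default 42, the cohort size
#'   the downstream proportion statistics assume).
#' @param condition_weights named nonnegative weights over condition labels;
#'   individuals are allocated to conditions by largest-remainder rounding of
#'   these weights. Defaults to the 6/14/5/15/8 FL/HL/CL/TL/TLA sample mix.
#' @param cell_types named list mapping type name to marker gene vector.
#'   Must contain `hepatocyte`, `cholangiocyte` and `LPC` entries.
#' @param marker_log2fc log2 fold-change planted for each marker in its own
#'   type (LPC additionally inherits the hepatocyte and cholangiocyte
#'   panels). Default 3.
#' @param reg_log2fc log2 fold-change planted in LPC cells for the 14-gene
#'   regeneration signature (see [regeneration_gene_set()]), which is always
#'   part of the gene universe. Default 1 — a mild program, distinct from
#'   the strong lineage markers.
#' @param baseline_freqs simplex vector over the non-LPC types (summing to 1
#'   within 1e-12), or a list of such vectors named by condition.
#' @param module_loadings optional matrix (non-LPC types x latent factors) of
#'   logit-scale loadings driving frequency covariation across individuals.
#' @param freq_noise_sd sd of i.i.d. logit noise on cluster frequencies.
#' @param lpc_fraction_mean,lpc_fraction_sd mean and sd of the planted
#'   per-individual LPC fraction among epithelial + LPC cells (defaults
#'   0.0295 and 0.0191); draws outside (0, 1) are clipped with a warning.
#' @param cells_per_individual cells simulated per individual.
#' @param n_genes total gene universe size (markers and mito genes included).
#' @param mito_gene_count number of mitochondrial (MT-) genes.
#' @param nb_dispersion negative-binomial dispersion phi (variance
#'   mu + phi mu^2); must be > 0.
#' @param libsize_log_mean,libsize_log_sd lognormal library-size parameters.
#' @param mito_beta_good,mito_beta_bad Beta(shape1, shape2) parameters of the
#'   per-cell mitochondrial count share for healthy and damaged cells.
#' @param lowq_cell_frac fraction of cells planted as low-quality (tiny
#'   library, high mito share) so the QC stage has true positives to remove.
#' @param contamination_beta_good,contamination_beta_bad Beta parameters of
#'   the ambient-contamination score for clean and contaminated cells.
#' @param contaminated_frac fraction of cells planted as contaminated.
#' @param doublet_beta_good,doublet_beta_bad Beta parameters of the doublet
#'   score for singlets and planted doublets.
#' @param doublet_rate fraction of cells planted as doublets (default 0.05).
#' @param seed integer seed; the generator is fully reproducible from it.
#' @param transcriptome_seed seed of the fixed gene-level baseline
#'   expression weights. Kept separate from `seed` so that independent
#'   cohorts share the same underlying transcriptome (as biological
#'   replicates would) while cells, compositions and noise are resampled.
#' @return A list of class `cohort_sim_config`.
#' @export
cohort_sim_config <- function(n_individuals = 42,
                              condition_weights = c(FL = 6, HL = 14, CL = 5,
                                                    TL = 15, TLA = 8),
                              cell_types = default_cell_types(),
                              marker_log2fc = 3,
                              reg_log2fc = 1,
                              baseline_freqs = NULL,
                              module_loadings = NULL,
                              freq_noise_sd = 0.3,
                              lpc_fraction_mean = 0.0295,
                              lpc_fraction_sd = 0.0191,
                              cells_per_individual = 400,
                              n_genes = 250,
                              mito_gene_count = 10,
                              nb_dispersion = 0.3,
                              libsize_log_mean = log(3000),
                              libsize_log_sd = 0.3,
                              mito_beta_good = c(8, 72),
                              mito_beta_bad = c(30, 20),
                              lowq_cell_frac = 0.02,
                              contamination_beta_good = c(2, 30),
                              contamination_beta_bad = c(12, 12),
                              contaminated_frac = 0.05,
                              doublet_beta_good = c(2, 20),
                              doublet_beta_bad = c(20, 4),
                              doublet_rate = 0.05,
                              seed = 1L,
                              transcriptome_seed = 101L) {
  if (!all(c("hepatocyte", "cholangiocyte", "LPC") %in% names(cell_types))) {
    stop_lpc("cell_types must include hepatocyte, cholangiocyte and LPC")
  }
  nonlpc <- setdiff(names(cell_types), "LPC")
  if (is.null(baseline_freqs)) {
    baseline_freqs <- c(hepatocyte = 0.35, cholangiocyte = 0.08,
                        endothelial = 0.15, HSC = 0.10, macrophage = 0.17,
                        T_cell = 0.10, B_cell = 0.05)[nonlpc]
  }
  if (!is.list(baseline_freqs)) {
    baseline_freqs <- stats::setNames(
      rep(list(baseline_freqs), length(condition_weights)),
      names(condition_weights))
  }
  for (cond in names(baseline_freqs)) {
    p <- baseline_freqs[[cond]]
    if (abs(sum(p) - 1) > 1e-12) {
      stop_lpc(sprintf("baseline_freqs for condition %s must sum to 1", cond))
    }
    if (!setequal(names(p), nonlpc)) {
      stop_lpc("baseline_freqs must be named by the non-LPC cell types")
    }
  }
  chk_scalar(lpc_fraction_mean, "lpc_fraction_mean", 0, 1,
             strict_lower = TRUE, strict_upper = TRUE)
  chk_scalar(nb_dispersion, "nb_dispersion", 0, strict_lower = TRUE)
  chk_scalar(doublet_rate, "doublet_rate", 0, 1)
  if (!is.null(module_loadings)) {
    module_loadings <- as.matrix(module_loadings)
    if (is.null(rownames(module_loadings)) ||
        !all(rownames(module_loadings) %in% nonlpc)) {
      stop_lpc("module_loadings rows must be named by non-LPC cell types")
    }
  }
  n_marker <- length(unique(c(unlist(cell_types), regeneration_gene_set())))
  if (n_genes < n_marker + mito_gene_count + 10) {
    stop_lpc("n_genes too small for the marker panels plus mito genes")
  }
  structure(as.list(environment()), class = "cohort_sim_config")
}

softmax <- function(eta) {
  e <- exp(eta - max(eta))
  e / sum(e)
}

#' Simulate per-unit cluster frequencies with planted factor structure
#'
#' The compositional core of the cohort generator, exposed on its own so the
#' cellular-module stage can be exercised directly: per sample unit, cluster
#' frequencies are softmax(logit(baseline) + loadings %*% f + noise) with f a
#' standard-normal latent factor vector, then cell counts are multinomial.
#' Clusters loading on the same factor therefore covary across units.
#'
#' @param n_units number of sample units (individuals).
#' @param baseline simplex vector of baseline cluster frequencies (named).
#' @param loadings matrix (clusters x factors) of logit-scale loadings;
#'   `NULL` for independent noise only.
#' @param noise_sd sd of i.i.d. logit noise.
#' @param cells_per_unit cells drawn per unit (multinomial size).
#' @param seed integer seed.
#' @return A list with `freq` (a `freq_table` of realized proportions,
#'   clusters x units), `counts` (cluster x unit cell counts), `expected`
#'   (pre-multinomial probabilities) and `factors` (units x factors draws).
#' @export
simulate_cluster_frequencies <- function(n_units, baseline, loadings = NULL,
                                         noise_sd = 0.3, cells_per_unit = 500,
                                         seed = 1L) {
  if (abs(sum(baseline) - 1) > 1e-12) stop_lpc("baseline must sum to 1")
  k <- length(baseline)
  if (is.null(names(baseline))) names(baseline) <- paste0("cluster", seq_len(k))
  local_seed(seed, {
    n_fac <- if (is.null(loadings)) 0L else ncol(as.matrix(loadings))
    fac <- if (n_fac > 0L) {
      matrix(stats::rnorm(n_units * n_fac), n_units, n_fac)
    } else {
      matrix(0, n_units, 0)
    }
    probs <- matrix(0, k, n_units, dimnames = list(names(baseline), NULL))
    cnt <- matrix(0L, k, n_units, dimnames = list(names(baseline), NULL))
    for (u in seq_len(n_units)) {
      eta <- stats::qlogis(baseline)
      if (n_fac > 0L) {
        L <- matrix(0, k, n_fac, dimnames = list(names(baseline), NULL))
        L[rownames(as.matrix(loadings)), ] <- as.matrix(loadings)
        eta <- eta + as.numeric(L %*% fac[u, ])
      }
      eta <- eta + stats::rnorm(k, sd = noise_sd)
      p <- softmax(eta)
      probs[, u] <- p
      cnt[, u] <- as.integer(stats::rmultinom(1, cells_per_unit, p))
    }
    colnames(probs) <- colnames(cnt) <- paste0("unit", seq_len(n_units))
    freq <- sweep(cnt, 2, colSums(cnt), "/")
    meta <- data.frame(unit = colnames(cnt),
                       individual = colnames(cnt),
                       condition = NA_character_,
                       stringsAsFactors = FALSE)
    list(freq = freq_table(freq, meta), counts = cnt, expected = probs,
         factors = fac)
  })
}

# deterministic largest-remainder allocation of n units to weighted groups
allocate_conditions <- function(n, weights) {
  q <- n * weights / sum(weights)
  base <- floor(q)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(q - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  rep(names(weights), times = base)
}

#' Simulate a single-cell liver cohort with planted ground truth
#'
#' Generates a full cohort: per-individual cluster frequencies from the
#' logistic-normal model, a planted per-individual LPC fraction of the merged
#' epithelial + LPC compartment, negative-binomial counts with marker
#' fold-changes (LPC cells co-express hepatocyte, cholangiocyte and
#' progenitor panels), mitochondrial genes, and Beta-distributed
#' contamination and doublet scores with a planted bad-cell mixture so QC
#' thresholds have true positives to act on. Truth labels (`true_type`, the
#' planted LPC fraction) are carried in the metadata separately from the
#' `cluster` column so recovery is measurable.
#'
#' @param config a [cohort_sim_config()].
#' @return A list with `expr` (a [cell_expr()]), `truth` (per-individual
#'   data.frame: condition, planted and realized LPC fraction, cell count)
#'   and `freq` (a `freq_table` of realized type frequencies, types x
#'   individuals).
#' @examples
#' sim <- simulate_cohort(cohort_sim_config(n_individuals = 4,
#'                                          cells_per_individual = 100))
#' dim(sim$expr)
#' head(sim$truth)
#' @export
simulate_cohort <- function(config = cohort_sim_config()) {
  stopifnot(inherits(config, "cohort_sim_config"))
  cfg <- config
  local_seed(cfg$seed, {
    types <- names(cfg$cell_types)
    nonlpc <- setdiff(types, "LPC")
    conds <- allocate_conditions(cfg$n_individuals, cfg$condition_weights)
    individuals <- sprintf("ind%02d", seq_len(cfg$n_individuals))

    # --- gene universe -----------------------------------------------------
    markers <- unique(unlist(cfg$cell_types))
    reg_extra <- setdiff(regeneration_gene_set(), markers)
    mito_genes <- sprintf("MT-G%d", seq_len(cfg$mito_gene_count))
    n_fill <- cfg$n_genes - length(markers) - length(reg_extra) -
      cfg$mito_gene_count
    fill <- sprintf("GENE%04d", seq_len(n_fill))
    genes <- c(markers, reg_extra, fill, mito_genes)
    is_mito <- genes %in% mito_genes
    marker_of <- rep(NA_character_, length(genes))
    for (t in types) {
      idx <- match(cfg$cell_types[[t]], genes)
      marker_of[idx] <- ifelse(is.na(marker_of[idx]), t,
                               paste(marker_of[idx], t, sep = ";"))
    }

    # base relative expression shared across types (lognormal weights);
    # fixed by its own seed so replicate cohorts share a transcriptome
    base_w <- local_seed(cfg$transcriptome_seed,
                         stats::rlnorm(length(genes), meanlog = 0, sdlog = 1))
    names(base_w) <- genes
    fc <- 2^cfg$marker_log2fc
    # per-type relative expression over NON-mito genes
    nonmito <- genes[!is_mito]
    type_p <- sapply(types, function(t) {
      w <- base_w[nonmito]
      up <- cfg$cell_types[[t]]
      if (t == "LPC") {
        up <- unique(c(up, cfg$cell_types$hepatocyte, cfg$cell_types$cholangiocyte))
      }
      w[intersect(up, nonmito)] <- w[intersect(up, nonmito)] * fc
      if (t == "LPC") {
        reg <- setdiff(intersect(regeneration_gene_set(), nonmito), up)
        w[reg] <- w[reg] * 2^cfg$reg_log2fc
      }
      w / sum(w)
    })
    mito_p <- base_w[mito_genes] / sum(base_w[mito_genes])

    # --- per-individual composition ---------------------------------------
    n_fac <- if (is.null(cfg$module_loadings)) 0L else ncol(cfg$module_loadings)
    truth <- data.frame(individual = individuals, condition = conds,
                        planted_lpc_fraction = NA_real_,
                        realized_lpc_fraction = NA_real_,
                        n_cells = NA_integer_, stringsAsFactors = FALSE)
    type_counts <- matrix(0L, length(types), cfg$n_individuals,
                          dimnames = list(types, individuals))
    clipped <- 0L
    for (i in seq_len(cfg$n_individuals)) {
      base <- cfg$baseline_freqs[[conds[i]]][nonlpc]
      eta <- stats::qlogis(base)
      if (n_fac > 0L) {
        L <- matrix(0, length(nonlpc), n_fac, dimnames = list(nonlpc, NULL))
        L[rownames(cfg$module_loadings), ] <- cfg$module_loadings
        eta <- eta + as.numeric(L %*% stats::rnorm(n_fac))
      }
      eta <- eta + stats::rnorm(length(nonlpc), sd = cfg$freq_noise_sd)
      p <- softmax(eta)
      f <- stats::rnorm(1, cfg$lpc_fraction_mean, cfg$lpc_fraction_sd)
      if (f <= 0 || f >= 1) {
        clipped <- clipped + 1L
        f <- min(max(f, 1e-4), 1 - 1e-4)
      }
      e <- p["hepatocyte"] + p["cholangiocyte"]
      l <- as.numeric(f * e / (1 - f + f * e))  # so l / (l + (1-l)e) = f
      q <- c(LPC = l, p * (1 - l))[types]
      type_counts[, i] <- as.integer(stats::rmultinom(1, cfg$cells_per_individual, q))
      truth$planted_lpc_fraction[i] <- f
    }
    if (clipped > 0L) {
      warning(sprintf("%d planted LPC fraction draw(s) outside (0,1) were clipped",
                      clipped))
    }
    epi <- type_counts["hepatocyte", ] + type_counts["cholangiocyte", ]
    truth$realized_lpc_fraction <-
      type_counts["LPC", ] / pmax(type_counts["LPC", ] + epi, 1)
    truth$n_cells <- colSums(type_counts)

    # --- cells -------------------------------------------------------------
    cell_type <- rep(rep(types, cfg$n_individuals), as.vector(type_counts))
    cell_ind <- rep(rep(individuals, each = length(types)), as.vector(type_counts))
    n_cells <- length(cell_type)
    cell_cond <- conds[match(cell_ind, individuals)]
    libsize <- stats::rlnorm(n_cells, cfg$libsize_log_mean, cfg$libsize_log_sd)
    lowq <- stats::runif(n_cells) < cfg$lowq_cell_frac
    libsize[lowq] <- libsize[lowq] * 0.03
    mito_share <- ifelse(lowq,
                         stats::rbeta(n_cells, cfg$mito_beta_bad[1], cfg$mito_beta_bad[2]),
                         stats::rbeta(n_cells, cfg$mito_beta_good[1], cfg$mito_beta_good[2]))

    size <- 1 / cfg$nb_dispersion
    counts <- matrix(0L, n_cells, length(genes),
                     dimnames = list(sprintf("cell%06d", seq_len(n_cells)), genes))
    ti <- match(cell_type, types)
    for (g in seq_along(nonmito)) {
      mu <- libsize * (1 - mito_share) * type_p[g, ti]
      counts[, nonmito[g]] <- stats::rnbinom(n_cells, mu = mu, size = size)
    }
    for (g in seq_along(mito_genes)) {
      mu <- libsize * mito_share * mito_p[g]
      counts[, mito_genes[g]] <- stats::rnbinom(n_cells, mu = mu, size = size)
    }

    contam_bad <- stats::runif(n_cells) < cfg$contaminated_frac
    contamination <- ifelse(contam_bad,
                            stats::rbeta(n_cells, cfg$contamination_beta_bad[1],
                                         cfg$contamination_beta_bad[2]),
                            stats::rbeta(n_cells, cfg$contamination_beta_good[1],
                                         cfg$contamination_beta_good[2]))
    dbl_bad <- stats::runif(n_cells) < cfg$doublet_rate
    doublet <- ifelse(dbl_bad,
                      stats::rbeta(n_cells, cfg$doublet_beta_bad[1],
                                   cfg$doublet_beta_bad[2]),
                      stats::rbeta(n_cells, cfg$doublet_beta_good[1],
                                   cfg$doublet_beta_good[2]))

    gene_meta <- data.frame(gene_id = genes, is_mito = is_mito,
                            marker_of = marker_of, stringsAsFactors = FALSE)
    expr <- cell_expr(counts,
                      data.frame(cell_id = rownames(counts),
                                 individual = cell_ind,
                                 condition = cell_cond,
                                 true_type = cell_type,
                                 cluster = cell_type,
                                 stringsAsFactors = FALSE),
                      gene_meta)
    expr$cell_meta$mito_fraction <- mito_fraction(expr)
    expr$cell_meta$contamination_score <- contamination
    expr$cell_meta$doublet_score <- doublet

    freq <- sweep(type_counts, 2, pmax(colSums(type_counts), 1), "/")
    meta <- data.frame(unit = individuals, individual = individuals,
                       condition = conds, stringsAsFactors = FALSE)
    list(expr = expr, truth = truth, freq = freq_table(freq, meta))
  })
}
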