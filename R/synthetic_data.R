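#' Parameters of the synthetic study generators
#'
#' One parameter object drives all three generators ([simulate_cohort()],
#' [simulate_invitro()], [simulate_sc()]). Defaults emulate the study
#' conditions of the motivating cohort design: 11 healthy / 57 tumor samples,
#' a latent per-tumor hypoxia level in \[0, 1\] driving a 27-gene program
#' (log2 effects Uniform(1.2, 2.5) at full hypoxia, chosen so the count score
#' separates h < 0.2 from h > 0.8 nearly perfectly while mid-range h is
#' ambiguous), a lymphatic-endothelial cell (LEC) fraction ~ Beta(2, 20)
#' confounding bulk candidate expression and read out by a PROX1-like marker,
#' an immune fraction ~ Beta(2, 5) with its 141-gene program, exponential
#' survival with hazard `lambda0 * exp(gamma * z_expr)` under uniform plus
#' administrative censoring, and a planted triple-positive candidate
#' transcript (`alpha_h = 1`, `gamma = 0.8`, induced in vitro).
#'
#' @param n_healthy,n_tumor Sample sizes (defaults 11 / 57).
#' @param n_decoys Null lncRNA decoys screened alongside the candidate (500).
#' @param h Optional fixed latent hypoxia vector for tumors (length
#'   `n_tumor`); default draws Uniform(0, 1). Healthy samples are always
#'   generated at h = 0.
#' @param beta_range log2 induction of each hypoxia program gene at h = 1.
#' @param baseline_range log2 baseline means of genes.
#' @param noise_sd Residual log2 noise sd (0.3).
#' @param candidate_name,candidate_baseline Planted candidate id and log2
#'   baseline (baseline 7 so the intensity > 6 criteria are attainable).
#' @param alpha_h Candidate log2 shift per unit latent hypoxia (1.0).
#' @param alpha_lec Candidate log2 shift per unit LEC fraction (4).
#' @param alpha_immune Candidate log2 shift per unit immune fraction (-1.5;
#'   negative, mirroring an inverse immune association).
#' @param gamma Log-hazard per sd of candidate expression (0.8).
#' @param lec_shape,immune_shape Beta parameters of the LEC and immune
#'   fractions.
#' @param marker_name,marker_intercept,marker_slope PROX1-like marker:
#'   log2 value = intercept + slope * LEC fraction + noise.
#' @param coupling_range Per-gene log2 coupling of the immune/stroma program
#'   genes to their fraction.
#' @param lambda0 Baseline hazard per day (log(2)/1500: median survival
#'   1500 days at average expression).
#' @param t_max Administrative censoring horizon in days (3650); independent
#'   censoring is Uniform(0, t_max).
#' @param recurrence_intercept,recurrence_slope Logistic model of recurrence
#'   on standardized candidate expression.
#' @param n_replicates In-vitro replicates per arm (5).
#' @param invitro_noise_sd In-vitro log2 noise sd (0.25).
#' @param invitro_lfc Planted in-vitro log2(hypoxia/normoxia) of the
#'   candidate (2.0, a strong four-fold induction).
#' @param control_gene,control_lfc Positive-control hypoxia gene in the
#'   in-vitro design.
#' @param sc_n_cells,sc_n_genes Single-cell matrix size (800 cells x 9000
#'   genes; the gene count exceeds the 7500-feature doublet rule so the rule
#'   is exercisable).
#' @param sc_clusters,sc_proportions Cluster labels and mixing proportions.
#' @param sc_markers LEC marker genes planted with LEC-specific expression.
#' @param sc_marker_mean,sc_marker_off Marker count mean inside/outside LEC.
#' @param sc_query Planted restricted transcript id (defaults to the
#'   candidate name).
#' @param restricted_fold Count-mean fold of the query in LEC over other
#'   clusters (20); `Inf` plants zero expression elsewhere.
#' @param sc_query_mean Query count mean in the LEC cluster (5).
#' @param sc_base_meanlog,sc_base_sdlog Log-normal background gene count
#'   means.
#' @param nb_size Negative-binomial size (dispersion) of counts.
#' @param libsize_sdlog Log-normal sd of per-cell library factors.
#' @param frac_low_feature,frac_doublet,frac_high_mito Fractions of cells
#'   planted to violate, respectively, the < 200-feature floor, the
#'   > 7500-feature ceiling and the > 5% mitochondrial rule (one rule each).
#' @param n_rare_genes Genes planted in fewer than 3 cells (exercises the
#'   gene floor).
#' @param n_ribo_genes Ribosomal (RPL/RPS-prefixed) genes planted.
#' @return list of parameters (class `sim_params`).
#' @export
sim_params <- function(n_healthy = 11, n_tumor = 57, n_decoys = 500,
                       h = NULL,
                       beta_range = c(1.2, 2.5), baseline_range = c(4, 10),
                       noise_sd = 0.3,
                       candidate_name = "LNC0001", candidate_baseline = 7,
                       alpha_h = 1.0, alpha_lec = 4, alpha_immune = -1.5,
                       gamma = 0.8,
                       lec_shape = c(2, 20), immune_shape = c(2, 5),
                       marker_name = "PROX1", marker_intercept = 4,
                       marker_slope = 10,
                       coupling_range = c(0.5, 2),
                       lambda0 = log(2) / 1500, t_max = 3650,
                       recurrence_intercept = -0.5, recurrence_slope = 1,
                       n_replicates = 5, invitro_noise_sd = 0.25,
                       invitro_lfc = 2.0,
                       control_gene = "CA9", control_lfc = 3,
                       sc_n_cells = 800, sc_n_genes = 9000,
                       sc_clusters = c("LEC", "BloodEC", "Epithelial",
                                       "Myeloid", "TNK", "Mesenchymal"),
                       sc_proportions = c(0.10, 0.15, 0.30, 0.20, 0.15, 0.10),
                       sc_markers = c("PROX1", "PDPN", "CDH5"),
                       sc_marker_mean = 5, sc_marker_off = 0.05,
                       sc_query = candidate_name,
                       restricted_fold = 20, sc_query_mean = 5,
                       sc_base_meanlog = log(0.15), sc_base_sdlog = 0.7,
                       nb_size = 2, libsize_sdlog = 0.3,
                       frac_low_feature = 0.02, frac_doublet = 0.02,
                       frac_high_mito = 0.02,
                       n_rare_genes = 30, n_ribo_genes = 20) {
  p <- as.list(environment())
  stopifnot(n_healthy >= 1, n_tumor >= 1, n_decoys >= 0,
            length(sc_clusters) == length(sc_proportions),
            abs(sum(sc_proportions) - 1) < 1e-8)
  if (!is.null(h) && length(h) != n_tumor)
    stop("fixed h must have length n_tumor")
  structure(p, class = "sim_params")
}

#' @keywords internal
runif_range <- function(n, range) stats::runif(n, range[1L], range[2L])

#' Simulate a bulk cohort with known ground truth
#'
#' Emits an aligned cohort (log2 expression + clinical table) whose rows are
#' the 27 hypoxia program genes, 141 immune and 141 stroma program genes, the
#' PROX1-like marker, the planted candidate and `n_decoys` null lncRNA
#' decoys. Healthy samples are generated at latent hypoxia h = 0; tumor
#' latent hypoxia is Uniform(0, 1) unless fixed via `params$h`. Survival
#' times are exponential with hazard `lambda0 * exp(gamma * z)` where z is
#' the tumor-standardized candidate expression; censoring is the minimum of a
#' Uniform(0, t_max) drop-out time and the administrative horizon.
#'
#' All randomness comes from one generator seeded at entry, so identical
#' seeds give identical cohorts.
#'
#' @param params A [sim_params()].
#' @param seed Integer seed.
#' @return list `cohort` (an `lnc_cohort`) and `truth` (latent `h`, `f_lec`,
#'   `f_immune`, `true_time` per tumor, and a per-transcript `transcripts`
#'   table of planted flags).
#' @export
simulate_cohort <- function(params = sim_params(), seed = 1) {
  stopifnot(inherits(params, "sim_params"))
  set.seed(seed)
  p <- params
  hyp_sig <- read_signature(signature_fixture("hypoxia_metagene_27"))
  imm_sig <- read_signature(signature_fixture("immune_141"))
  str_sig <- read_signature(signature_fixture("stroma_141"))

  healthy_ids <- sprintf("H%02d", seq_len(p$n_healthy))
  tumor_ids <- sprintf("T%03d", seq_len(p$n_tumor))
  samples <- c(healthy_ids, tumor_ids)
  n <- length(samples)

  h <- c(rep(0, p$n_healthy),
         if (is.null(p$h)) stats::runif(p$n_tumor) else p$h)
  f_lec <- stats::rbeta(n, p$lec_shape[1L], p$lec_shape[2L])
  f_imm <- stats::rbeta(n, p$immune_shape[1L], p$immune_shape[2L])

  decoys <- if (p$n_decoys > 0)
    sprintf("LNC%04d", seq_len(p$n_decoys) + 1L) else character(0)
  genes <- unique(c(hyp_sig$genes, imm_sig$genes, str_sig$genes,
                    p$marker_name, p$candidate_name, decoys))

  base <- runif_range(length(genes), p$baseline_range)
  names(base) <- genes
  base[p$candidate_name] <- p$candidate_baseline

  expr <- matrix(base, nrow = length(genes), ncol = n,
                 dimnames = list(genes, samples))
  beta <- runif_range(length(hyp_sig$genes), p$beta_range)
  expr[hyp_sig$genes, ] <- expr[hyp_sig$genes, ] + outer(beta, h)
  c_imm <- runif_range(length(imm_sig$genes), p$coupling_range)
  expr[imm_sig$genes, ] <- expr[imm_sig$genes, ] + outer(c_imm, f_imm)
  c_str <- runif_range(length(str_sig$genes), p$coupling_range)
  expr[str_sig$genes, ] <- expr[str_sig$genes, ] + outer(c_str, f_lec)
  expr[p$marker_name, ] <- p$marker_intercept + p$marker_slope * f_lec
  expr[p$candidate_name, ] <- expr[p$candidate_name, ] +
    p$alpha_h * h + p$alpha_lec * f_lec + p$alpha_immune * f_imm
  expr <- expr + matrix(stats::rnorm(length(expr), sd = p$noise_sd),
                        nrow = nrow(expr))

  cand_t <- expr[p$candidate_name, tumor_ids]
  z <- if (stats::sd(cand_t) > 0) as.vector(scale(cand_t)) else rep(0, p$n_tumor)
  hazard <- p$lambda0 * exp(p$gamma * z)
  true_time <- stats::rexp(p$n_tumor, rate = hazard)
  censor <- pmin(stats::runif(p$n_tumor, 0, p$t_max), p$t_max)
  os_time <- pmin(true_time, censor)
  os_event <- as.integer(true_time <= censor)
  rec_p <- stats::plogis(p$recurrence_intercept + p$recurrence_slope * z)
  recurrence <- ifelse(stats::rbinom(p$n_tumor, 1L, rec_p) == 1L, "yes", "no")
  stage <- sample(c("I", "II"), p$n_tumor, replace = TRUE)

  clinical <- data.frame(
    sample = samples,
    tissue = c(rep("healthy", p$n_healthy), rep("tumor", p$n_tumor)),
    os_time = c(rep(NA_real_, p$n_healthy), round(os_time, 1)),
    os_event = c(rep(NA_integer_, p$n_healthy), os_event),
    recurrence = c(rep(NA_character_, p$n_healthy), recurrence),
    stage = c(rep(NA_character_, p$n_healthy), stage),
    stringsAsFactors = FALSE)

  cohort <- suppressMessages(align_cohort(expr, clinical))
  truth <- list(
    h = stats::setNames(h, samples),
    f_lec = stats::setNames(f_lec, samples),
    f_immune = stats::setNames(f_imm, samples),
    true_time = stats::setNames(true_time, tumor_ids),
    beta = stats::setNames(beta, hyp_sig$genes),
    transcripts = data.frame(
      transcript = c(p$candidate_name, decoys),
      hypoxia_coupled = c(p$alpha_h != 0, rep(FALSE, length(decoys))),
      prognostic = c(p$gamma != 0, rep(FALSE, length(decoys))),
      invitro_induced = c(p$invitro_lfc != 0, rep(FALSE, length(decoys))),
      lec_coupled = c(p$alpha_lec != 0, rep(FALSE, length(decoys))),
      stringsAsFactors = FALSE))
  list(cohort = cohort, truth = truth)
}

#' Simulate a paired normoxia/hypoxia in-vitro experiment
#'
#' Gene universe matches [simulate_cohort()] plus a positive-control hypoxia
#' gene. Under hypoxia the 27 program genes shift by their full-program
#' effects, the control gene by `control_lfc`, and the planted candidate by
#' `invitro_lfc`; decoys and the immune/stroma/marker genes do not respond.
#'
#' @param params A [sim_params()].
#' @param seed Integer seed.
#' @return list `expr` (log2 matrix, genes x 2*n_replicates samples),
#'   `normoxia_ids`, `hypoxia_ids`, `truth` (planted log2FC per gene).
#' @export
simulate_invitro <- function(params = sim_params(), seed = 1) {
  stopifnot(inherits(params, "sim_params"))
  if (params$n_replicates < 2) stop("need n_replicates >= 2")
  set.seed(seed + 1L)
  p <- params
  hyp_sig <- read_signature(signature_fixture("hypoxia_metagene_27"))
  imm_sig <- read_signature(signature_fixture("immune_141"))
  str_sig <- read_signature(signature_fixture("stroma_141"))
  decoys <- if (p$n_decoys > 0)
    sprintf("LNC%04d", seq_len(p$n_decoys) + 1L) else character(0)
  genes <- unique(c(hyp_sig$genes, imm_sig$genes, str_sig$genes,
                    p$marker_name, p$control_gene, p$candidate_name, decoys))

  base <- runif_range(length(genes), p$baseline_range)
  names(base) <- genes
  base[p$candidate_name] <- p$candidate_baseline
  base[p$control_gene] <- max(base[p$control_gene], 7)

  lfc <- stats::setNames(rep(0, length(genes)), genes)
  lfc[hyp_sig$genes] <- runif_range(length(hyp_sig$genes), p$beta_range)
  lfc[p$control_gene] <- p$control_lfc
  lfc[p$candidate_name] <- p$invitro_lfc

  nx_ids <- sprintf("Nx%d", seq_len(p$n_replicates))
  hx_ids <- sprintf("Hx%d", seq_len(p$n_replicates))
  mu <- cbind(matrix(base, length(genes), p$n_replicates),
              matrix(base + lfc, length(genes), p$n_replicates))
  expr <- mu + matrix(stats::rnorm(length(mu), sd = p$invitro_noise_sd),
                      nrow = nrow(mu))
  dimnames(expr) <- list(genes, c(nx_ids, hx_ids))
  list(expr = expr, normoxia_ids = nx_ids, hypoxia_ids = hx_ids,
       truth = list(planted_lfc = lfc,
                    induced = names(lfc)[lfc != 0]))
}

#' Simulate a generic two-group expression experiment
#'
#' Utility generator for differential-expression calibration: `n_genes`
#' genes at log2 baselines Uniform(`baseline_range`), of which the named
#' `planted_lfc` genes are shifted in group 2 and (so the intensity criterion
#' is attainable) given baselines Uniform(`planted_intensity_range`). Used
#' for type-I/FDR simulations (empty `planted_lfc`) and for xenograft-style
#' DEG fixtures (e.g. 74 planted genes of which 63 negative).
#'
#' @param n_genes Total genes.
#' @param planted_lfc Named numeric vector of planted log2 fold changes
#'   (may be empty).
#' @param n_per_group Samples per group.
#' @param noise_sd Log2 noise sd.
#' @param baseline_range,planted_intensity_range Log2 baseline ranges for
#'   null and planted genes.
#' @param seed Integer seed.
#' @return list `expr`, `group1_ids`, `group2_ids`, `truth`.
#' @export
simulate_de_experiment <- function(n_genes = 1000, planted_lfc = numeric(0),
                                   n_per_group = 4, noise_sd = 0.25,
                                   baseline_range = c(4, 10),
                                   planted_intensity_range = c(7, 10),
                                   seed = 1) {
  set.seed(seed + 2L)
  if (length(planted_lfc) > 0 && is.null(names(planted_lfc)))
    names(planted_lfc) <- sprintf("PLANT%04d", seq_along(planted_lfc))
  n_null <- n_genes - length(planted_lfc)
  if (n_null < 0) stop("n_genes smaller than the planted set")
  genes <- c(names(planted_lfc), sprintf("NULL%05d", seq_len(n_null)))
  base <- c(runif_range(length(planted_lfc), planted_intensity_range),
            runif_range(n_null, baseline_range))
  lfc <- c(planted_lfc, rep(0, n_null))
  g1 <- sprintf("A%d", seq_len(n_per_group))
  g2 <- sprintf("B%d", seq_len(n_per_group))
  mu <- cbind(matrix(base, n_genes, n_per_group),
              matrix(base + lfc, n_genes, n_per_group))
  expr <- mu + matrix(stats::rnorm(length(mu), sd = noise_sd), nrow = n_genes)
  dimnames(expr) <- list(genes, c(g1, g2))
  list(expr = expr, group1_ids = g1, group2_ids = g2,
       truth = list(planted_lfc = lfc[lfc != 0]))
}

#' Simulate a clustered single-cell count matrix with known ground truth
#'
#' Counts are negative binomial around per-(cluster, gene) means scaled by
#' log-normal per-cell library factors. The planted query transcript is
#' expressed in the LEC-like cluster at `restricted_fold` times its mean in
#' every other cluster (`Inf` = zero elsewhere); the marker genes (PROX1,
#' PDPN, CDH5-like) are LEC-specific. Configurable fractions of cells are
#' planted to violate exactly one QC rule each (feature floor, feature
#' ceiling, mitochondrial percentage), and a small set of genes is planted in
#' fewer than 3 cells; mitochondrial (MT-) and ribosomal (RPL/RPS) genes are
#' present so the prefix rules are exercised.
#'
#' @param params A [sim_params()].
#' @param seed Integer seed.
#' @return list `sc` (an `sc_matrix`), `truth` (per-rule planted violator
#'   barcodes, planted rare genes, query/marker names, cluster labels).
#' @export
simulate_sc <- function(params = sim_params(), seed = 1) {
  stopifnot(inherits(params, "sim_params"))
  set.seed(seed + 3L)
  p <- params
  if (length(p$sc_clusters) < 2L) stop("need >= 2 clusters")
  if (!"LEC" %in% p$sc_clusters) stop("cluster set must include an LEC-like cluster")

  mt_genes <- paste0("MT-", c("ND1", "ND2", "CO1", "CO2", "ATP6", "ATP8",
                              "CYB", "ND3", "ND4", "ND4L", "ND5", "ND6", "CO3"))
  ribo_genes <- paste0(rep(c("RPL", "RPS"), length.out = p$n_ribo_genes),
                       seq_len(p$n_ribo_genes))
  rare_genes <- sprintf("RARE%03d", seq_len(p$n_rare_genes))
  special <- c(p$sc_query, p$sc_markers, mt_genes, ribo_genes, rare_genes)
  n_bg <- p$sc_n_genes - length(special)
  if (n_bg <= 0) stop("sc_n_genes too small for the planted gene sets")
  genes <- c(special, sprintf("G%05d", seq_len(n_bg)))

  n_cells <- p$sc_n_cells
  barcodes <- sprintf("CELL%04d", seq_len(n_cells))
  cluster <- sample(p$sc_clusters, n_cells, replace = TRUE,
                    prob = p$sc_proportions)
  donor <- sample(sprintf("D%d", 1:4), n_cells, replace = TRUE)
  tissue <- sample(c("tumor", "adjacent"), n_cells, replace = TRUE)

  # per-gene base means; MT genes pinned so normal cells sit near 2% mito
  base_mean <- stats::rlnorm(length(genes), p$sc_base_meanlog, p$sc_base_sdlog)
  names(base_mean) <- genes
  base_mean[mt_genes] <- 2.8
  base_mean[ribo_genes] <- 2
  base_mean[rare_genes] <- 0
  base_mean[p$sc_markers] <- p$sc_marker_off
  base_mean[p$sc_query] <- if (is.finite(p$restricted_fold))
    p$sc_query_mean / p$restricted_fold else 0

  # planted QC violators: disjoint sets, one rule each
  n_low <- round(p$frac_low_feature * n_cells)
  n_dbl <- round(p$frac_doublet * n_cells)
  n_mito <- round(p$frac_high_mito * n_cells)
  viol <- sample(barcodes, n_low + n_dbl + n_mito)
  low_cells <- viol[seq_len(n_low)]
  dbl_cells <- viol[n_low + seq_len(n_dbl)]
  mito_cells <- viol[n_low + n_dbl + seq_len(n_mito)]

  lib <- stats::rlnorm(n_cells, 0, p$libsize_sdlog)
  names(lib) <- barcodes
  lib[low_cells] <- 0.05   # ~70 detected genes, far below the 200 floor
  lib[dbl_cells] <- 30     # ~8000 detected genes, far above the 7500 ceiling

  mu <- outer(base_mean, lib)
  lec <- cluster == "LEC"
  mu[p$sc_markers, lec] <- p$sc_marker_mean * rep(lib[lec], each = length(p$sc_markers))
  mu[p$sc_query, lec] <- p$sc_query_mean * lib[lec]
  mu[mt_genes, mito_cells] <- mu[mt_genes, mito_cells] * 8

  counts <- matrix(stats::rnbinom(length(mu), mu = mu, size = p$nb_size),
                   nrow = nrow(mu), dimnames = list(genes, barcodes))
  counts[mt_genes, low_cells] <- 0L  # keep feature-floor violators clean of the mito rule
  # rare genes: one count in 1-2 well-behaved cells each
  normal <- setdiff(barcodes, viol)
  for (g in rare_genes)
    counts[g, sample(normal, sample(1:2, 1L))] <- 1L

  ann <- data.frame(barcode = barcodes, cluster = cluster, donor = donor,
                    tissue = tissue, stringsAsFactors = FALSE)
  sc <- sc_matrix(counts, ann)
  truth <- list(low_feature_cells = low_cells, doublet_cells = dbl_cells,
                high_mito_cells = mito_cells, rare_genes = rare_genes,
                ribo_genes = ribo_genes, query = p$sc_query,
                markers = p$sc_markers, restricted_fold = p$restricted_fold,
                cluster = stats::setNames(cluster, barcodes))
  list(sc = sc, truth = truth)
}
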