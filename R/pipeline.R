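#' Default pipeline configuration
#'
#' Assembles the configuration for [run_pipeline()] with every analysis
#' threshold at its standard value: CPM filter 0.5, FDR 0.05, trans
#' clustering window 2 cM, hotspot threshold 30 genes, pcQTL threshold
#' 1e-5. Scale parameters default to a compact synthetic study; the
#' configuration round-trips losslessly through JSON.
#'
#' @param seed global seed expanded into per-stage substreams.
#' @param n_lines,n_chrom,chrom_length_cM,n_markers,n_genes,n_per_family,n_parental
#'   synthetic-study scale (see [founder_panel()], [simulate_truth()]).
#' @param sigma_alpha,dominance_ratio,Ve generating cis architecture (see
#'   [random_cis_architecture()]).
#' @param cpm_threshold,fdr,trans_window_cM,hotspot_min_genes,pcqtl_p
#'   analysis thresholds.
#' @param n_series maximum genes carried into allelic-series selection.
#' @param n_pairs background gene pairs for the covariance stage.
#' @param n_pc principal components scanned for pcQTLs.
#' @param stages character vector of stages to run (dependency order is
#'   enforced; a stage whose prerequisite is excluded fails with a message).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1, n_lines = 10, n_chrom = 2,
                            chrom_length_cM = 90, n_markers = 120,
                            n_genes = 60, n_per_family = 40, n_parental = 2,
                            sigma_alpha = 0.5, dominance_ratio = 0, Ve = 1,
                            cpm_threshold = 0.5, fdr = 0.05,
                            trans_window_cM = 2, hotspot_min_genes = 30,
                            pcqtl_p = 1e-5, n_series = 5, n_pairs = 100,
                            n_pc = 2,
                            stages = c("simulate", "genotype", "normalize",
                                       "fit_cis", "allele_series", "ase",
                                       "covariance", "pca", "seqvar")) {
  cfg <- as.list(environment())
  class(cfg) <- "pipeline_config"
  cfg
}

#' Write / read a pipeline configuration
#'
#' @param config a `pipeline_config`.
#' @param path JSON file path.
#' @return `read_pipeline_config` returns the configuration.
#' @export
write_pipeline_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  class(cfg) <- "pipeline_config"
  cfg
}

write_tsv <- function(x, dir, name) {
  utils::write.table(x, file.path(dir, paste0(name, ".tsv")), sep = "\t",
                     quote = FALSE, row.names = is.matrix(x))
}

#' Run the analysis pipeline end-to-end
#'
#' Executes the stages in dependency order on a synthetic study: simulate ->
#' genotype (per-family HMM, maps, interpolation, relatedness) -> normalize
#' (CPM filter, Box-Cox, standardize) -> cis fits (Models 0/1/2 with FDR) ->
#' allelic series -> allele-specific expression -> pairwise covariances ->
#' PCA and pcQTL scan -> sequence-variation regression. Every stage writes
#' its result tables as TSV under `out_dir` and a JSON manifest records the
#' configuration, seeds and per-stage timing. Re-running with the same
#' configuration reproduces the outputs exactly.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if needed); `NULL` skips writing.
#' @return named list with each executed stage's in-memory results plus the
#'   manifest.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  need <- function(stage, dep, res) {
    if (is.null(res[[dep]]))
      stop("stage '", stage, "' needs stage '", dep,
           "', which is disabled or failed", call. = FALSE)
  }
  on <- function(s) s %in% config$stages
  res <- list()
  timing <- c()
  tic <- function(expr) { t0 <- proc.time()[3]; v <- force(expr); attr(v, "elapsed") <- proc.time()[3] - t0; v }

  if (on("simulate")) {
    t0 <- proc.time()[3]
    panel <- founder_panel(config$n_lines, 1, config$n_chrom,
                           config$chrom_length_cM, config$n_markers,
                           config$n_genes)
    arch <- random_cis_architecture(panel, config$sigma_alpha,
                                    config$dominance_ratio, config$Ve,
                                    rng_seed = substream_seed(config$seed, 10L))
    study <- simulate_study(panel, arch, config$n_per_family,
                            config$n_parental,
                            rng_seed = substream_seed(config$seed, 11L))
    res$simulate <- list(panel = panel, arch = arch, study = study)
    timing["simulate"] <- proc.time()[3] - t0
    if (!is.null(out_dir)) {
      write_tsv(study$design, out_dir, "design")
      write_tsv(study$dose, out_dir, "truth_genotypes")
      write_tsv(study$gene_ref, out_dir, "gene_ref_counts")
      write_tsv(study$gene_alt, out_dir, "gene_alt_counts")
    }
  }

  if (on("genotype")) {
    need("genotype", "simulate", res)
    t0 <- proc.time()[3]
    study <- res$simulate$study
    loci <- study$loci
    mk <- loci$type == "marker"
    marker_pos <- loci[mk, ]
    gene_pos <- loci[!mk, ]
    fams <- sort(unique(study$design$family[study$design$generation == "F2"]))
    decoded_dose <- matrix(NA_integer_, nrow(study$dose), sum(mk),
                           dimnames = list(rownames(study$dose),
                                           loci$id[mk]))
    gene_geno <- matrix(NA_integer_, nrow(study$dose), sum(!mk),
                        dimnames = list(rownames(study$dose), loci$id[!mk]))
    maps <- list()
    for (z in fams) {
      sel <- study$design$family == z
      gt <- genotype_family(study$marker_ref[sel, , drop = FALSE],
                            study$marker_alt[sel, , drop = FALSE],
                            marker_pos, gene_pos)
      decoded_dose[sel, ] <- gt$decoded - 1L
      gene_geno[sel, ] <- gt$gene_genotypes - 1L
      maps[[as.character(z)]] <- gt$map
    }
    # parental reference plants are homozygous reference throughout
    pref <- study$design$family == 0L
    decoded_dose[pref, ] <- 0L; gene_geno[pref, ] <- 0L
    K <- relatedness(decoded_dose, study$design$family)
    res$genotype <- list(marker_dose = decoded_dose, gene_dose = gene_geno,
                         maps = maps, K = K, Keig = eigen_kinship(K))
    timing["genotype"] <- proc.time()[3] - t0
    if (!is.null(out_dir)) {
      write_tsv(decoded_dose, out_dir, "marker_genotypes")
      write_tsv(gene_geno, out_dir, "gene_genotypes")
      write_tsv(unclass(K), out_dir, "relatedness")
    }
  }

  if (on("normalize")) {
    need("normalize", "simulate", res)
    t0 <- proc.time()[3]
    study <- res$simulate$study
    total <- study$gene_ref + study$gene_alt
    prep <- prepare_expression(total, cpm_threshold = config$cpm_threshold)
    res$normalize <- prep
    timing["normalize"] <- proc.time()[3] - t0
    if (!is.null(out_dir)) {
      write_tsv(prep$phenotype, out_dir, "phenotype")
      write_tsv(prep$transforms, out_dir, "transforms")
    }
  }

  if (on("fit_cis")) {
    need("fit_cis", "genotype", res)
    need("fit_cis", "normalize", res)
    t0 <- proc.time()[3]
    study <- res$simulate$study
    ph <- res$normalize$phenotype
    gd <- res$genotype$gene_dose
    fam <- study$design$family
    coh <- study$design$cohort
    rows <- list()
    for (g in colnames(ph)) {
      ct <- cis_tests(ph[, g], gd[, g], fam, coh,
                      if (anyNA(gd[, g])) res$genotype$K else res$genotype$Keig,
                      config$n_lines, 1)
      rows[[g]] <- if (isTRUE(ct$untestable))
        data.frame(gene = g, LRT1 = NA, p1 = NA, LRT2 = NA, p2 = NA,
                   Vg_cis_r2 = NA, Vg_cis_a = NA, Vg_trans = NA, Ve = NA)
      else
        data.frame(gene = g, LRT1 = ct$LRT1, p1 = ct$p1, LRT2 = ct$LRT2,
                   p2 = ct$p2, Vg_cis_r2 = ct$Vg_cis_r2,
                   Vg_cis_a = ct$Vg_cis_a, Vg_trans = ct$Vg_trans,
                   Ve = ct$Ve)
    }
    tab <- do.call(rbind, rows)
    tab$q1 <- bh_fdr(tab$p1)
    tab$q2 <- bh_fdr(tab$p2)
    res$fit_cis <- tab
    timing["fit_cis"] <- proc.time()[3] - t0
    if (!is.null(out_dir)) write_tsv(tab, out_dir, "cis_results")
  }

  if (on("allele_series")) {
    need("allele_series", "fit_cis", res)
    t0 <- proc.time()[3]
    tab <- res$fit_cis
    study <- res$simulate$study
    ph <- res$normalize$phenotype
    gd <- res$genotype$gene_dose
    sig <- tab$gene[!is.na(tab$q1) & tab$q1 < config$fdr]
    sig <- intersect(sig, colnames(gd)[colSums(is.na(gd)) == 0])
    sig <- utils::head(sig, config$n_series)
    series <- lapply(sig, function(g)
      select_series(ph[, g], gd[, g], study$design$family,
                    study$design$cohort, res$genotype$Keig,
                    n_lines = config$n_lines))
    names(series) <- sig
    st <- data.frame(gene = sig,
                     k = vapply(series, `[[`, numeric(1), "k"),
                     H = vapply(series, `[[`, numeric(1), "H"))
    res$allele_series <- list(series = series, table = st)
    timing["allele_series"] <- proc.time()[3] - t0
    if (!is.null(out_dir)) write_tsv(st, out_dir, "allele_series")
  }

  if (on("ase")) {
    need("ase", "genotype", res)
    t0 <- proc.time()[3]
    study <- res$simulate$study
    gd <- res$genotype$gene_dose
    fam <- study$design$family
    rows <- list()
    for (g in colnames(study$gene_ref)) for (z in sort(unique(fam[fam > 0]))) {
      sel <- which(fam == z & !is.na(gd[, g]) & gd[, g] == 1L &
                     (study$gene_ref[, g] + study$gene_alt[, g]) > 0)
      if (length(sel) < 2) next
      ft <- ase_test(study$gene_ref[sel, g], study$gene_alt[sel, g])
      rows[[length(rows) + 1L]] <- data.frame(
        gene = g, family = z, n = ft$n_plants, mu = ft$mu, naive = ft$naive,
        LRT = ft$LRT, p = ft$p)
    }
    at <- do.call(rbind, rows)
    at$q <- bh_fdr(at$p)
    res$ase <- at
    timing["ase"] <- proc.time()[3] - t0
    if (!is.null(out_dir)) write_tsv(at, out_dir, "ase_results")
  }

  if (on("covariance")) {
    need("covariance", "normalize", res)
    need("covariance", "genotype", res)
    t0 <- proc.time()[3]
    ph <- res$normalize$phenotype
    pairs <- random_pairs(colnames(ph), k = 2,
                          rng_seed = substream_seed(config$seed, 12L))
    pairs <- utils::head(pairs, config$n_pairs)
    coh <- stats::model.matrix(~cohort, res$simulate$study$design)
    pc <- pair_covariances(pairs, ph, res$genotype$Keig, coh)
    res$covariance <- pc
    timing["covariance"] <- proc.time()[3] - t0
    if (!is.null(out_dir)) write_tsv(pc, out_dir, "pair_covariances")
  }

  if (on("pca")) {
    need("pca", "normalize", res)
    need("pca", "genotype", res)
    t0 <- proc.time()[3]
    study <- res$simulate$study
    ph <- res$normalize$phenotype
    gd <- res$genotype$gene_dose
    loci <- study$loci
    gp <- loci[match(colnames(gd), loci$id), ]
    pcs <- pca_transcriptome(ph, n_pc = config$n_pc)
    scans <- lapply(seq_len(ncol(pcs$scores)), function(j)
      pc_qtl_scan(pcs$scores[, j], gd, gp,
                  study$design$family, study$design$cohort,
                  res$genotype$K, p_threshold = config$pcqtl_p,
                  n_lines = config$n_lines))
    res$pca <- list(pcs = pcs, scans = scans)
    timing["pca"] <- proc.time()[3] - t0
    if (!is.null(out_dir)) {
      write_tsv(pcs$scores, out_dir, "pc_scores")
      write_tsv(do.call(rbind, lapply(seq_along(scans), function(j)
        cbind(PC = j, scans[[j]]$by_chrom))), out_dir, "pcqtl")
    }
  }

  if (on("seqvar")) {
    need("seqvar", "fit_cis", res)
    t0 <- proc.time()[3]
    sums <- simulate_window_summaries(res$simulate$arch,
                                      rng_seed = substream_seed(config$seed, 13L))
    agg <- aggregate_window_stats(sums)
    tab <- res$fit_cis
    m <- match(tab$gene, agg$gene)
    ok <- !is.na(tab$LRT1) & !is.na(m)
    reg <- predict_cis_significance(tab$LRT1[ok],
                                    agg[m[ok], -1, drop = FALSE],
                                    log_response = TRUE)
    res$seqvar <- list(summaries = agg, regression = reg)
    timing["seqvar"] <- proc.time()[3] - t0
    if (!is.null(out_dir)) {
      write_tsv(agg, out_dir, "window_stats")
      write_tsv(as.data.frame(reg$coefficients), out_dir, "seqvar_regression")
    }
  }

  manifest <- list(
    package = "f2eqtl",
    version = as.character(utils::packageVersion("f2eqtl")),
    r_version = R.version.string,
    config = unclass(config),
    timing_s = as.list(round(timing, 3)),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  res$manifest <- manifest
  if (!is.null(out_dir))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  res
}
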