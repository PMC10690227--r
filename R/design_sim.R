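#' Define a founder panel for a replicated F2 design
#'
#' A replicated F2 design crosses one reference inbred line to each of several
#' alternative inbred lines; a single F1 per cross is selfed to produce an F2
#' family in which exactly two founder haplotypes segregate. The panel records
#' the founder lines, the chromosomes with their genetic map lengths, and the
#' positions of genotyping markers and expressed genes on a shared cM
#' coordinate system.
#'
#' @param n_lines number of fully inbred founder lines (reference included).
#' @param reference_line index of the reference line common to all crosses.
#' @param n_chrom number of chromosomes.
#' @param chrom_length_cM genetic length of each chromosome in centimorgans
#'   (recycled to `n_chrom`).
#' @param n_markers total number of genotyping markers, spread evenly across
#'   chromosomes and positioned uniformly along each.
#' @param n_genes total number of expressed genes, interleaved with markers.
#' @param bp_per_cM physical scale used to assign bp coordinates.
#' @return an object of class `founder_panel`: a list with `n_lines`,
#'   `reference_line`, `chromosomes` (data frame `name`, `length_cM`) and
#'   `loci` (data frame `id`, `type`, `chrom`, `cM`, `bp`, ordered by
#'   chromosome then position).
#' @export
founder_panel <- function(n_lines = 10, reference_line = 1, n_chrom = 2,
                          chrom_length_cM = 90, n_markers = 500,
                          n_genes = 300, bp_per_cM = 250000) {
  stopifnot(n_lines >= 2, reference_line >= 1, reference_line <= n_lines,
            n_chrom >= 1, all(chrom_length_cM >= 0), n_markers >= 2)
  len <- rep_len(chrom_length_cM, n_chrom)
  mk_per <- diff(round(seq(0, n_markers, length.out = n_chrom + 1)))
  gn_per <- diff(round(seq(0, n_genes, length.out = n_chrom + 1)))
  rows <- vector("list", n_chrom)
  for (ch in seq_len(n_chrom)) {
    m <- mk_per[ch]; g <- gn_per[ch]
    # evenly spaced, genes offset half a step from markers so they interleave
    mpos <- seq(0, len[ch], length.out = max(m, 2L))
    gpos <- if (g > 0) seq(0, len[ch], length.out = g + 2L)[-c(1L, g + 2L)] else numeric(0)
    df <- rbind(
      data.frame(type = "marker", cM = mpos),
      if (g > 0) data.frame(type = "gene", cM = gpos)
    )
    df$chrom <- ch
    rows[[ch]] <- df[order(df$cM, df$type), ]
  }
  loci <- do.call(rbind, rows)
  loci$bp <- round(loci$cM * bp_per_cM)
  nm <- loci$type == "marker"
  loci$id <- NA_character_
  loci$id[nm] <- sprintf("M%04d", seq_len(sum(nm)))
  loci$id[!nm] <- sprintf("G%04d", seq_len(sum(!nm)))
  rownames(loci) <- loci$id
  structure(list(n_lines = n_lines, reference_line = reference_line,
                 chromosomes = data.frame(name = paste0("chr", seq_len(n_chrom)),
                                          length_cM = len),
                 loci = loci[, c("id", "type", "chrom", "cM", "bp")]),
            class = "founder_panel")
}

#' @export
print.founder_panel <- function(x, ...) {
  cat("Founder panel:", x$n_lines, "inbred lines (reference line",
      x$reference_line, ")\n")
  cat(nrow(x$chromosomes), "chromosome(s),",
      sum(x$loci$type == "marker"), "markers,",
      sum(x$loci$type == "gene"), "genes,",
      sum(x$chromosomes$length_cM), "cM total\n")
  invisible(x)
}

#' Simulate crossover positions for meiotic gametes
#'
#' Crossovers are placed under the Haldane model (no interference): the count
#' per gamete is Poisson with mean `map_length_cM / 100` and positions are
#' uniform on the chromosome. A diploid F2 chromosome is the union of two
#' independent gametes, so at the study's average chromosome length of 90 cM
#' it carries about 1.8 crossovers.
#'
#' @param map_length_cM chromosome genetic length in centimorgans (>= 0).
#' @param n_gametes number of independent gametes to draw.
#' @param rng_seed optional integer seed; `NULL` uses the current RNG state.
#' @return a list of length `n_gametes` of numeric vectors of sorted crossover
#'   positions in cM.
#' @export
simulate_meiosis <- function(map_length_cM, n_gametes = 1, rng_seed = NULL) {
  if (!is.numeric(map_length_cM) || length(map_length_cM) != 1 ||
      is.na(map_length_cM) || map_length_cM < 0)
    stop("'map_length_cM' must be a single non-negative number")
  if (!is.null(rng_seed)) set.seed(rng_seed)
  k <- stats::rpois(n_gametes, map_length_cM / 100)
  lapply(k, function(ki) sort(stats::runif(ki, 0, map_length_cM)))
}

# allele (0 = reference, 1 = alternative) carried by a gamete at positions pos,
# given its crossover positions and the allele at position 0
gamete_allele <- function(pos, crossovers, start) {
  (start + findInterval(pos, crossovers)) %% 2L
}

#' Simulate one F2 family by selfing an F1
#'
#' The F1 of a reference x alternative cross is heterozygous at every locus.
#' Each F2 plant is formed from two independent F1 gametes, with crossovers
#' placed by [simulate_meiosis()]. Genotypes are returned as the dose (0, 1,
#' 2) of the alternative-line allele at every locus of the panel; at any
#' single locus the expected segregation is 1:2:1.
#'
#' @param panel a [founder_panel()].
#' @param alt_line index of the alternative founder (not the reference line).
#' @param n_plants number of F2 plants (> 0).
#' @param rng_seed optional integer seed.
#' @return matrix `n_plants x n_loci` of alternative-allele doses, with loci
#'   in panel order and `alt_line` kept as an attribute.
#' @export
simulate_f2_family <- function(panel, alt_line, n_plants, rng_seed = NULL) {
  stopifnot(inherits(panel, "founder_panel"))
  if (alt_line == panel$reference_line)
    stop("'alt_line' must differ from the reference line")
  if (!is.numeric(n_plants) || n_plants <= 0)
    stop("'n_plants' must be a positive integer")
  if (!is.null(rng_seed)) set.seed(rng_seed)
  loci <- panel$loci
  dose <- matrix(0L, n_plants, nrow(loci),
                 dimnames = list(NULL, loci$id))
  for (ch in seq_len(nrow(panel$chromosomes))) {
    sel <- which(loci$chrom == ch)
    pos <- loci$cM[sel]
    L <- panel$chromosomes$length_cM[ch]
    for (i in seq_len(n_plants)) {
      g1 <- gamete_allele(pos, simulate_meiosis(L)[[1]], stats::rbinom(1, 1, 0.5))
      g2 <- gamete_allele(pos, simulate_meiosis(L)[[1]], stats::rbinom(1, 1, 0.5))
      dose[i, sel] <- g1 + g2
    }
  }
  attr(dose, "alt_line") <- alt_line
  dose
}

#' Specify a generating genetic architecture for expression
#'
#' The architecture holds everything the expression simulator needs beyond the
#' genotypes: per-gene cis effects with the genotypic-value parameterisation 0
#' (reference homozygote), `a + d` (heterozygote) and `2a` (alternative
#' homozygote); trans effects tied to causal loci; environmental variance; the
#' read-depth model; and the coupling between cis effects and allele-specific
#' read fractions in heterozygotes.
#'
#' @param panel a [founder_panel()].
#' @param cis_a,cis_d `n_genes x n_lines` matrices of additive and dominance
#'   effects per alternative line (phenotype SD units); the reference column
#'   is forced to zero. A scalar is recycled; `NULL` means all zero.
#' @param m per-gene intercept (recycled).
#' @param Ve per-gene environmental variance (recycled, >= 0).
#' @param trans data frame of trans effects with columns `locus` (a locus id
#'   from the panel), `gene` (a gene id), `a`, `d` and optionally `lines`
#'   (comma-separated alternative-line indices carrying the causal variant;
#'   `NA` means every alternative line carries it).
#' @param cohort_effects fixed additive effect of each growth cohort.
#' @param depth read-depth model: mean/sd of per-gene and per-marker log
#'   abundance (reads per plant), sd of the per-plant log library-size factor,
#'   and the negative-binomial dispersion (0 gives Poisson).
#' @param ase_coupling if `TRUE`, the alternative-allele read fraction in a
#'   cis heterozygote is `plogis(ase_strength * a_z)` instead of 0.5, so the
#'   high-expressing allele is over-represented in its own transcripts.
#' @param ase_strength logistic slope of that coupling.
#' @return an object of class `f2_architecture`.
#' @export
architecture <- function(panel, cis_a = NULL, cis_d = NULL, m = 0, Ve = 1,
                         trans = NULL, cohort_effects = rep(0, 4),
                         depth = list(gene_meanlog = log(50), gene_sdlog = 1,
                                      marker_meanlog = log(25), marker_sdlog = 0.7,
                                      libsize_sdlog = 0.1, dispersion = 0.05),
                         ase_coupling = FALSE, ase_strength = 1) {
  stopifnot(inherits(panel, "founder_panel"))
  genes <- panel$loci$id[panel$loci$type == "gene"]
  G <- length(genes)
  L <- panel$n_lines
  expand <- function(x, what) {
    if (is.null(x)) x <- 0
    if (is.matrix(x)) {
      stopifnot(nrow(x) == G, ncol(x) == L)
    } else {
      x <- matrix(x, G, L)
    }
    if (any(!is.finite(x))) stop("non-finite ", what, " effects")
    x[, panel$reference_line] <- 0
    dimnames(x) <- list(genes, paste0("line", seq_len(L)))
    x
  }
  cis_a <- expand(cis_a, "additive")
  cis_d <- expand(cis_d, "dominance")
  Ve <- rep_len(Ve, G)
  if (any(Ve < 0)) stop("'Ve' must be non-negative")
  if (!is.null(trans)) {
    stopifnot(all(c("locus", "gene", "a", "d") %in% names(trans)))
    if (!all(trans$locus %in% panel$loci$id))
      stop("trans record references an unknown locus")
    if (!all(trans$gene %in% genes))
      stop("trans record references an unknown gene")
    if (any(!is.finite(trans$a)) || any(!is.finite(trans$d)))
      stop("non-finite trans effects")
    if (is.null(trans$lines)) trans$lines <- NA_character_
  }
  structure(list(panel = panel, genes = genes, cis_a = cis_a, cis_d = cis_d,
                 m = rep_len(m, G), Ve = Ve, trans = trans,
                 cohort_effects = cohort_effects, depth = depth,
                 ase_coupling = isTRUE(ase_coupling),
                 ase_strength = ase_strength),
            class = "f2_architecture")
}

#' Draw a random cis architecture with exchangeable founder effects
#'
#' Each founder haplotype of each gene receives an iid Normal(0,
#' `sigma_alpha^2`) allelic effect; the cis additive effect of alternative
#' line z is the difference from the reference haplotype. Under this
#' exchangeable-founder model the additive genetic variance contributed by the
#' cis locus of a gene is `2 * sigma_alpha^2` in expectation, which is the
#' quantity the locus-variance estimators target.
#'
#' @param panel a [founder_panel()].
#' @param sigma_alpha SD of per-haplotype effects (phenotype SD units).
#' @param dominance_ratio per-line `d/a` ratio applied to every cis effect.
#' @param Ve environmental variance.
#' @param rng_seed optional seed.
#' @param ... further arguments passed to [architecture()].
#' @return an `f2_architecture` with an `alpha` attribute holding the drawn
#'   haplotype effects.
#' @export
random_cis_architecture <- function(panel, sigma_alpha = 0.5,
                                    dominance_ratio = 0, Ve = 1,
                                    rng_seed = NULL, ...) {
  if (!is.null(rng_seed)) set.seed(rng_seed)
  G <- sum(panel$loci$type == "gene")
  alpha <- matrix(stats::rnorm(G * panel$n_lines, 0, sigma_alpha),
                  G, panel$n_lines)
  a <- alpha - alpha[, panel$reference_line]
  arch <- architecture(panel, cis_a = a, cis_d = dominance_ratio * a,
                       Ve = Ve, ...)
  attr(arch, "alpha") <- alpha
  arch
}

#' Simulate genotype truth for a whole replicated F2 study
#'
#' Simulates every F2 family plus replicate plants of each parental line, and
#' assembles the design table. Parental plants are homozygous at every locus
#' (dose 0 for the reference line, dose 2 within the family block of their own
#' line).
#'
#' @param panel a [founder_panel()].
#' @param n_per_family F2 plants per family.
#' @param n_parental plants per parental line (0 to omit parental lines).
#' @param n_cohorts number of growth cohorts plants are cycled through.
#' @param rng_seed integer seed; per-family substreams are derived from it so
#'   any family can be regenerated alone.
#' @return an object of class `f2_truth`: list with `design` (plant_id,
#'   family, cohort, generation; family 0 marks reference-line parentals),
#'   `dose` (plants x loci alternative-allele dose), `loci`, `panel`.
#' @export
simulate_truth <- function(panel, n_per_family = 150, n_parental = 4,
                           n_cohorts = 4, rng_seed = 1) {
  stopifnot(inherits(panel, "founder_panel"))
  alt_lines <- setdiff(seq_len(panel$n_lines), panel$reference_line)
  blocks <- list(); fam <- integer(0); gen <- character(0)
  for (z in alt_lines) {
    d <- simulate_f2_family(panel, z, n_per_family,
                            rng_seed = substream_seed(rng_seed, 1L, z))
    blocks[[length(blocks) + 1L]] <- d
    fam <- c(fam, rep(z, n_per_family))
    gen <- c(gen, rep("F2", n_per_family))
  }
  if (n_parental > 0) {
    n_loci <- nrow(panel$loci)
    blocks[[length(blocks) + 1L]] <-
      matrix(0L, n_parental, n_loci, dimnames = list(NULL, panel$loci$id))
    fam <- c(fam, rep(0L, n_parental)); gen <- c(gen, rep("P", n_parental))
    for (z in alt_lines) {
      blocks[[length(blocks) + 1L]] <-
        matrix(2L, n_parental, n_loci, dimnames = list(NULL, panel$loci$id))
      fam <- c(fam, rep(z, n_parental)); gen <- c(gen, rep("P", n_parental))
    }
  }
  dose <- do.call(rbind, blocks)
  n <- nrow(dose)
  design <- data.frame(
    plant_id = sprintf("pl%05d", seq_len(n)),
    family = fam,
    cohort = factor(((seq_len(n) - 1L) %% n_cohorts) + 1L),
    generation = gen, stringsAsFactors = FALSE)
  rownames(dose) <- design$plant_id
  structure(list(design = design, dose = dose, loci = panel$loci,
                 panel = panel), class = "f2_truth")
}

# genotypic value a*dose + d*het for one effect applied to a dose vector
.genotypic_value <- function(dose, a, d) a * dose + d * (dose == 1L)

#' Simulate expression and allele-specific read counts
#'
#' Builds the latent phenotype of every plant at every gene (cis genotypic
#' value + trans genotypic values + cohort effect + Normal environmental
#' noise), then draws read counts around an exp-scaled abundance with a
#' negative-binomial depth model, and splits the reads of cis heterozygotes
#' binomially between the two parental alleles. Homozygotes emit reads only
#' from their own allele; putative-call miscalls are modelled downstream (see
#' [inject_miscalls()]), matching the HMM's emission abstraction. Marker loci
#' receive allele-specific counts with no genetic effect on their own totals.
#'
#' @param truth an `f2_truth` from [simulate_truth()].
#' @param arch an `f2_architecture` on the same panel.
#' @param rng_seed integer seed.
#' @return an object of class `f2_study`: the truth fields plus `phenotype`
#'   (plants x genes latent values), `gene_ref`/`gene_alt` and
#'   `marker_ref`/`marker_alt` count matrices, `lib_factor`, and the
#'   architecture used.
#' @export
simulate_expression <- function(truth, arch, rng_seed = 1) {
  stopifnot(inherits(truth, "f2_truth"), inherits(arch, "f2_architecture"))
  if (!identical(truth$loci$id, arch$panel$loci$id))
    stop("architecture and genotype truth use different loci")
  set.seed(substream_seed(rng_seed, 2L, 0L))
  design <- truth$design
  n <- nrow(design)
  genes <- arch$genes
  G <- length(genes)
  fam <- design$family
  dep <- arch$depth

  # latent phenotypes
  gene_abund <- exp(stats::rnorm(G, dep$gene_meanlog, dep$gene_sdlog))
  lib <- exp(stats::rnorm(n, 0, dep$libsize_sdlog))
  coh <- arch$cohort_effects[as.integer(design$cohort)]
  Y <- matrix(0, n, G, dimnames = list(design$plant_id, genes))
  a_plant <- matrix(0, n, G)  # per-plant cis additive effect (for ASE coupling)
  for (g in seq_len(G)) {
    dose_g <- truth$dose[, genes[g]]
    a <- ifelse(fam == 0L, 0, arch$cis_a[g, pmax(fam, 1L)])
    d <- ifelse(fam == 0L, 0, arch$cis_d[g, pmax(fam, 1L)])
    Y[, g] <- arch$m[g] + a * dose_g + d * (dose_g == 1L) +
      coh + stats::rnorm(n, 0, sqrt(arch$Ve[g]))
    a_plant[, g] <- a
  }
  if (!is.null(arch$trans)) {
    for (k in seq_len(nrow(arch$trans))) {
      tr <- arch$trans[k, ]
      g <- match(tr$gene, genes)
      carriers <- if (is.na(tr$lines)) setdiff(seq_len(arch$panel$n_lines),
                                               arch$panel$reference_line)
                  else as.integer(strsplit(tr$lines, ",")[[1]])
      in_fam <- fam %in% carriers
      dose_l <- truth$dose[, tr$locus]
      Y[in_fam, g] <- Y[in_fam, g] +
        .genotypic_value(dose_l[in_fam], tr$a, tr$d)
    }
  }

  draw_counts <- function(mu, dispersion) {
    if (dispersion > 0) stats::rnbinom(length(mu), mu = mu, size = 1 / dispersion)
    else stats::rpois(length(mu), mu)
  }
  split_counts <- function(total, dose, p_alt) {
    alt <- integer(length(total))
    alt[dose == 2L] <- total[dose == 2L]
    het <- which(dose == 1L)
    if (length(het))
      alt[het] <- stats::rbinom(length(het), total[het], p_alt[het])
    alt
  }

  gene_ref <- gene_alt <- matrix(0L, n, G, dimnames = dimnames(Y))
  for (g in seq_len(G)) {
    mu <- gene_abund[g] * lib * exp(Y[, g] - arch$m[g])
    total <- draw_counts(mu, dep$dispersion)
    p_alt <- if (arch$ase_coupling)
      stats::plogis(arch$ase_strength * a_plant[, g]) else rep(0.5, n)
    alt <- split_counts(total, truth$dose[, genes[g]], p_alt)
    gene_alt[, g] <- alt
    gene_ref[, g] <- total - alt
  }

  markers <- truth$loci$id[truth$loci$type == "marker"]
  M <- length(markers)
  marker_abund <- exp(stats::rnorm(M, dep$marker_meanlog, dep$marker_sdlog))
  marker_ref <- marker_alt <- matrix(0L, n, M,
                                     dimnames = list(design$plant_id, markers))
  for (m in seq_len(M)) {
    total <- draw_counts(marker_abund[m] * lib, dep$dispersion)
    alt <- split_counts(total, truth$dose[, markers[m]], rep(0.5, n))
    marker_alt[, m] <- alt
    marker_ref[, m] <- total - alt
  }

  structure(c(truth[c("design", "dose", "loci", "panel")],
              list(phenotype = Y, gene_ref = gene_ref, gene_alt = gene_alt,
                   marker_ref = marker_ref, marker_alt = marker_alt,
                   lib_factor = lib, arch = arch)),
            class = c("f2_study", "f2_truth"))
}

#' Simulate a complete synthetic study
#'
#' Convenience wrapper: [simulate_truth()] followed by
#' [simulate_expression()].
#'
#' @inheritParams simulate_truth
#' @inheritParams simulate_expression
#' @return an `f2_study`.
#' @export
simulate_study <- function(panel, arch, n_per_family = 150, n_parental = 4,
                           n_cohorts = 4, rng_seed = 1) {
  truth <- simulate_truth(panel, n_per_family, n_parental, n_cohorts, rng_seed)
  simulate_expression(truth, arch, rng_seed)
}

#' Corrupt putative genotype calls with miscalls
#'
#' Flips each non-missing call to one of the two other genotype states with
#' equal probability at the given rate, emulating genotyping error at the
#' level of the emitted putative call (the abstraction the HMM's emission
#' model works at).
#'
#' @param calls integer matrix of calls (1 = RR, 2 = RA, 3 = AA, `NA`
#'   missing).
#' @param rate per-call miscall probability in `[0, 1]`.
#' @param rng_seed optional seed.
#' @return matrix of the same shape with miscalls injected.
#' @export
inject_miscalls <- function(calls, rate, rng_seed = NULL) {
  stopifnot(rate >= 0, rate <= 1)
  if (!is.null(rng_seed)) set.seed(rng_seed)
  flip <- !is.na(calls) & stats::runif(length(calls)) < rate
  idx <- which(flip)
  if (length(idx)) {
    wrong <- vapply(calls[idx],
                    function(s) sample(setdiff(1:3, s), 1L), integer(1))
    calls[idx] <- wrong
  }
  calls
}

#' Benchmark locus-variance estimators on a fixed genotype framework
#'
#' Repeats, on the realized genotype matrix of a simulated study, the draw of
#' a cis-QTL phenotype under an exchangeable-founder allelic model (each
#' founder haplotype gets an iid Normal effect, redrawn per replicate, so the
#' locus's genetic values have covariance `Va * R_locus` with
#' `Va = 2 sigma_alpha^2`) and re-estimates the locus variance with
#' Haseman-Elston regression on the locus-specific relatedness, the
#' model-contrast estimator Vg(r2) and the effect-dispersion estimator
#' Vg(a). All three estimators see identical replicates.
#'
#' @param study an `f2_truth` or `f2_study` providing genotypes and design.
#' @param scenarios named list of scenarios; each a list with elements
#'   `sigma_alpha` (per-haplotype effect SD), `Ve` (residual variance,
#'   default 1), `vg_bg` (background polygenic variance spread over the
#'   genome-wide relatedness, default 0) and optionally `locus` (a locus id;
#'   default the middle marker of chromosome 1).
#' @param n_reps replicates per scenario (>= 2).
#' @param rng_seed integer seed.
#' @param K optional precomputed relatedness matrix (else computed from the
#'   marker doses).
#' @param estimators subset of `c("HE", "Vg_r2", "Vg_a")`.
#' @return data frame with one row per scenario x estimator: `truth`,
#'   `mean_est`, `bias`, `var`, `mse`, `n_reps`.
#' @export
estimator_benchmark <- function(study, scenarios, n_reps, rng_seed = 1,
                                K = NULL,
                                estimators = c("HE", "Vg_r2", "Vg_a")) {
  stopifnot(inherits(study, "f2_truth"))
  if (n_reps < 2) stop("'n_reps' must be at least 2")
  bad <- setdiff(estimators, c("HE", "Vg_r2", "Vg_a"))
  if (length(bad)) stop("unknown estimator(s): ", paste(bad, collapse = ", "))
  design <- study$design
  n <- nrow(design)
  markers <- study$loci$id[study$loci$type == "marker"]
  if (is.null(K))
    K <- relatedness(study$dose[, markers, drop = FALSE], design$family)
  Keig <- eigen_kinship(K)
  Lch <- if (any(vapply(scenarios, function(s) !is.null(s$vg_bg) && s$vg_bg > 0,
                        logical(1)))) chol(K + diag(1e-8, n)) else NULL
  X0 <- stats::model.matrix(~cohort, design)
  n_lines <- study$panel$n_lines
  ref <- study$panel$reference_line
  fam <- design$family
  set.seed(rng_seed)
  out <- list()
  for (sc_name in names(scenarios)) {
    sc <- scenarios[[sc_name]]
    sigma_alpha <- sc$sigma_alpha
    Ve <- if (is.null(sc$Ve)) 1 else sc$Ve
    vg_bg <- if (is.null(sc$vg_bg)) 0 else sc$vg_bg
    locus <- if (is.null(sc$locus))
      markers[ceiling(sum(study$loci$chrom[study$loci$type == "marker"] == 1) / 2)]
    else sc$locus
    dose <- study$dose[, locus]
    R_locus <- unclass(relatedness(matrix(dose, ncol = 1), fam,
                                   psd_repair = FALSE))
    truth_v <- 2 * sigma_alpha^2
    est <- matrix(NA_real_, n_reps, 3,
                  dimnames = list(NULL, c("HE", "Vg_r2", "Vg_a")))
    for (r in seq_len(n_reps)) {
      alpha <- stats::rnorm(n_lines, 0, sigma_alpha)
      # genetic value: (2 - dose) copies of the reference haplotype effect
      # plus dose copies of the family's alternative haplotype effect
      g <- (2 - dose) * alpha[ref] +
        dose * ifelse(fam == 0L, alpha[ref], alpha[pmax(fam, 1L)])
      y <- g + stats::rnorm(n, 0, sqrt(Ve))
      if (vg_bg > 0) y <- y + sqrt(vg_bg) * drop(crossprod(Lch, stats::rnorm(n)))
      if ("HE" %in% estimators)
        est[r, "HE"] <- he_regression(stats::resid(stats::lm.fit(X0, y)),
                                      R_locus)
      if (any(c("Vg_r2", "Vg_a") %in% estimators)) {
        fit0 <- fit_lmm(y, X0, Keig)
        X1 <- cbind(X0, family_dose_design(dose, fam, n_lines, ref))
        fit1 <- fit_lmm(y, X1, Keig)
        est[r, "Vg_r2"] <- vg_r2(fit0, fit1)
        acols <- grep("^a_line", colnames(X1))
        est[r, "Vg_a"] <- vg_a(fit1$beta[acols], fit1$se[acols])
      }
    }
    for (e in estimators) {
      v <- est[, e]
      out[[length(out) + 1L]] <- data.frame(
        scenario = sc_name, estimator = e, truth = truth_v,
        mean_est = mean(v), bias = mean(v) - truth_v,
        var = stats::var(v), mse = mean((v - truth_v)^2), n_reps = n_reps)
    }
  }
  do.call(rbind, out)
}
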