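#' Describe a synthetic cessation cohort
#'
#' Defaults reproduce the design of the study cohort: 9 nonsmokers,
#' 10 smokers sampled again as quitters after cessation, 1100 assayed
#' miRNAs of which 25 are planted up- and 9 down-regulated by smoking,
#' with 12 of the 34 (persist_fraction ~ 0.353) remaining dysregulated
#' after cessation. The expression model is additive on the log2 scale:
#' baseline + group effect + gender effect + Gaussian noise (log-normal
#' intensities), optionally with a subject random intercept.
#'
#' @param n_nonsmoker,n_smoker Group sizes; quitters are the same
#'   `n_smoker` subjects resampled after cessation.
#' @param n_mirna Total number of miRNA features.
#' @param n_up,n_down Planted smoking up-/down-regulated features.
#' @param persist_fraction Fraction of planted features that remain
#'   dysregulated in quitters, in [0, 1].
#' @param effect_log2 Planted smoking effect, log2 scale.
#' @param gender_effect_log2 Additive gender effect (added to male samples),
#'   log2 scale; applied to all features.
#' @param noise_sd_log2 Residual standard deviation, log2 scale.
#' @param baseline_mean_log2 Global mean log2 intensity.
#' @param subject_sd_log2 Subject random-intercept standard deviation
#'   (0 disables the paired correlation).
#' @param seed Integer seed; all generation derives from it.
#' @return A list of class `cohort_design`.
#' @export
cohort_design <- function(n_nonsmoker = 9L, n_smoker = 10L, n_mirna = 1100L,
                          n_up = 25L, n_down = 9L, persist_fraction = 12 / 34,
                          effect_log2 = 1.5, gender_effect_log2 = 0.3,
                          noise_sd_log2 = 0.5, baseline_mean_log2 = 7,
                          subject_sd_log2 = 0, seed = 1L) {
  d <- list(n_nonsmoker = as.integer(n_nonsmoker), n_smoker = as.integer(n_smoker),
            n_mirna = as.integer(n_mirna), n_up = as.integer(n_up),
            n_down = as.integer(n_down), persist_fraction = persist_fraction,
            effect_log2 = effect_log2, gender_effect_log2 = gender_effect_log2,
            noise_sd_log2 = noise_sd_log2, baseline_mean_log2 = baseline_mean_log2,
            subject_sd_log2 = subject_sd_log2, seed = as.integer(seed))
  if (d$n_nonsmoker < 2L || d$n_smoker < 2L) stop("need at least 2 samples per group")
  if (d$n_mirna < 1L) stop("n_mirna must be positive")
  if (d$n_up < 0L || d$n_down < 0L || d$n_up + d$n_down > d$n_mirna)
    stop("n_up + n_down must lie in [0, n_mirna]")
  if (d$persist_fraction < 0 || d$persist_fraction > 1)
    stop("persist_fraction must be in [0, 1]")
  if (d$noise_sd_log2 <= 0) stop("noise_sd_log2 must be > 0")
  if (d$subject_sd_log2 < 0) stop("subject_sd_log2 must be >= 0")
  if (!is.finite(d$effect_log2) || !is.finite(d$gender_effect_log2) ||
      !is.finite(d$baseline_mean_log2))
    stop("effects and baseline must be finite")
  class(d) <- "cohort_design"
  d
}

# alternate M/F within a group, mirroring the near-balanced cohort (4/5, 5/5)
.alternating_gender <- function(n, start = "M") {
  rep_len(if (start == "M") c("M", "F") else c("F", "M"), n)
}

#' Generate a synthetic cessation cohort
#'
#' Produces a log2 expression matrix for nonsmokers, baseline smokers and
#' the same subjects after cessation, the matching metadata table, and a
#' ground-truth table of planted directions and persistence. Planted up/down
#' features shift the smoker_baseline group by +/- `effect_log2`; persistent
#' features keep the shift in quitter samples while reversible features
#' return to baseline. Quitter residual noise is drawn fresh, so with
#' `subject_sd_log2 = 0` the pairing carries no artificial correlation.
#'
#' @param design A [cohort_design()].
#' @return list with elements `expr` (matrix, miRNAs x samples), `meta`
#'   (data.frame: sample_id, subject_id, group, gender) and `truth`
#'   (data.frame: mirna_id, direction in up/down/null, persistence in
#'   persistent/reversible/not_applicable).
#' @export
generate_cohort <- function(design) {
  if (!inherits(design, "cohort_design")) stop("design must be a cohort_design")
  d <- design
  set.seed(d$seed)

  mirna_ids <- sprintf("mir-%04d", seq_len(d$n_mirna))
  direction <- rep("null", d$n_mirna)
  if (d$n_up > 0L) direction[seq_len(d$n_up)] <- "up"
  if (d$n_down > 0L) direction[d$n_up + seq_len(d$n_down)] <- "down"

  n_planted <- d$n_up + d$n_down
  n_persist <- as.integer(round(d$persist_fraction * n_planted))
  n_persist_up <- min(d$n_up, as.integer(round(d$persist_fraction * d$n_up)))
  n_persist_down <- min(d$n_down, n_persist - n_persist_up)
  persistence <- rep("not_applicable", d$n_mirna)
  persistence[direction != "null"] <- "reversible"
  if (n_persist_up > 0L)
    persistence[sample(which(direction == "up"), n_persist_up)] <- "persistent"
  if (n_persist_down > 0L)
    persistence[sample(which(direction == "down"), n_persist_down)] <- "persistent"

  ns_ids <- sprintf("NS%02d", seq_len(d$n_nonsmoker))
  sm_subj <- sprintf("S%02d", seq_len(d$n_smoker))
  meta <- data.frame(
    sample_id = c(ns_ids, paste0(sm_subj, "_base"), paste0(sm_subj, "_quit")),
    subject_id = c(ns_ids, sm_subj, sm_subj),
    group = factor(rep(.group_levels, times = c(d$n_nonsmoker, d$n_smoker, d$n_smoker)),
                   levels = .group_levels),
    gender = c(.alternating_gender(d$n_nonsmoker, "M"),
               rep(.alternating_gender(d$n_smoker, "M"), 2L)),
    stringsAsFactors = FALSE)

  n_samp <- nrow(meta)
  shift <- ifelse(direction == "up", d$effect_log2,
                  ifelse(direction == "down", -d$effect_log2, 0))
  # per-(feature, sample) group effect: baseline smokers always shifted,
  # quitters only when the feature is persistent
  grp_eff <- matrix(0, d$n_mirna, n_samp)
  grp_eff[, meta$group == "smoker_baseline"] <- shift
  grp_eff[persistence == "persistent", meta$group == "quitter"] <-
    shift[persistence == "persistent"]

  gender_eff <- matrix(rep(ifelse(meta$gender == "M", d$gender_effect_log2, 0),
                           each = d$n_mirna), d$n_mirna, n_samp)
  subj_eff <- 0
  if (d$subject_sd_log2 > 0) {
    subj <- unique(meta$subject_id)
    u <- stats::rnorm(length(subj), 0, d$subject_sd_log2)
    subj_eff <- matrix(rep(u[match(meta$subject_id, subj)], each = d$n_mirna),
                       d$n_mirna, n_samp)
  }
  noise <- matrix(stats::rnorm(d$n_mirna * n_samp, 0, d$noise_sd_log2),
                  d$n_mirna, n_samp)
  expr <- d$baseline_mean_log2 + grp_eff + gender_eff + subj_eff + noise
  dimnames(expr) <- list(mirna_ids, meta$sample_id)

  truth <- data.frame(mirna_id = mirna_ids, direction = direction,
                      persistence = persistence, stringsAsFactors = FALSE)
  list(expr = expr, meta = meta, truth = truth)
}

#' Generate annotation resources matched to a ground-truth table
#'
#' Builds the three annotation inputs the enrichment stage consumes:
#' a miRNA category collection in which one category (`planted_category`)
#' is enriched for the planted dysregulated miRNAs at a configurable fold,
#' a miRNA-to-gene target map over a synthetic gene universe with a
#' designated pathway collection in which one pathway (`planted_pathway`)
#' is enriched for targets of the persistent miRNAs, and an RPKM table
#' whose values straddle the expressed-gene threshold of 0.125 RPKM.
#'
#' @param truth Truth table from [generate_cohort()].
#' @param n_categories Number of miRNA categories (>= 1; the first is planted).
#' @param category_size Members per category.
#' @param planted_category_fold Approximate fold-enrichment of planted
#'   miRNAs in the planted category (>= 1).
#' @param n_genes Synthetic gene universe size.
#' @param targets_per_mirna Predicted targets drawn per miRNA.
#' @param n_pathways Number of gene pathways (>= 1; the first is planted).
#' @param pathway_size Genes per pathway.
#' @param planted_pathway_overlap Fraction of the planted pathway drawn
#'   from persistent-miRNA targets, in [0, 1].
#' @param expressed_fraction Fraction of genes with RPKM above 0.125.
#' @param seed Integer seed.
#' @return list with `categories` (as [read_gene_sets()] returns, universe =
#'   number of miRNAs), `target_map` (data.frame mirna_id/gene_id),
#'   `pathways` (gene-set list, universe = `n_genes`), `rpkm` (named vector).
#' @export
generate_annotation_resources <- function(truth,
                                          n_categories = 10L, category_size = 40L,
                                          planted_category_fold = 6,
                                          n_genes = 2000L, targets_per_mirna = 30L,
                                          n_pathways = 10L, pathway_size = 50L,
                                          planted_pathway_overlap = 0.6,
                                          expressed_fraction = 0.8, seed = 1L) {
  set.seed(as.integer(seed))
  mirnas <- truth$mirna_id
  n_mirna <- length(mirnas)
  if (category_size > n_mirna) stop("category size exceeds the miRNA universe")
  if (pathway_size > n_genes) stop("pathway size exceeds the gene universe")

  planted <- mirnas[truth$direction != "null"]
  # planted category: hit rate = fold * (category_size / n_mirna), capped
  p_hit <- min(1, planted_category_fold * category_size / n_mirna)
  n_hit <- min(length(planted), category_size, as.integer(round(p_hit * length(planted))))
  cat_members <- c(sample(planted, n_hit),
                   sample(setdiff(mirnas, planted), category_size - n_hit))
  categories <- list(planted_category = cat_members)
  if (n_categories > 1L) {
    for (i in seq_len(n_categories - 1L))
      categories[[sprintf("category_%02d", i)]] <- sample(mirnas, category_size)
  }

  genes <- sprintf("gene%05d", seq_len(n_genes))
  target_map <- data.frame(
    mirna_id = rep(mirnas, each = targets_per_mirna),
    gene_id = unlist(lapply(seq_len(n_mirna),
                            function(i) sample(genes, targets_per_mirna))),
    stringsAsFactors = FALSE)
  target_map <- unique(target_map)

  persistent <- mirnas[truth$persistence == "persistent"]
  persist_targets <- unique(target_map$gene_id[target_map$mirna_id %in% persistent])
  n_overlap <- min(length(persist_targets),
                   as.integer(round(planted_pathway_overlap * pathway_size)))
  pw_members <- c(sample(persist_targets, n_overlap),
                  sample(setdiff(genes, persist_targets), pathway_size - n_overlap))
  pathways <- list(planted_pathway = pw_members)
  if (n_pathways > 1L) {
    for (i in seq_len(n_pathways - 1L))
      pathways[[sprintf("pathway_%02d", i)]] <- sample(genes, pathway_size)
  }

  # log-uniform RPKM above/below the 0.125 expressed-gene cut
  n_expr <- as.integer(round(expressed_fraction * n_genes))
  rpkm <- numeric(n_genes)
  hi <- sample.int(n_genes, n_expr)
  rpkm[hi] <- 10 ^ stats::runif(n_expr, log10(0.13), 3)
  rpkm[-hi] <- 10 ^ stats::runif(n_genes - n_expr, -3, log10(0.12))
  names(rpkm) <- genes

  list(categories = structure(list(sets = categories, universe_size = n_mirna),
                              universe_derived = FALSE),
       target_map = target_map,
       pathways = structure(list(sets = pathways, universe_size = as.integer(n_genes)),
                            universe_derived = FALSE),
       rpkm = rpkm)
}
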