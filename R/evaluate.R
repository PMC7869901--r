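#' Confusion-matrix metrics
#'
#' Accuracy, sensitivity, false-positive rate and precision of a binary
#' classifier:
#' ACC = (TP + TN) / total, SN = TP / (TP + FN),
#' FPR = FP / (FP + TN), PREC = TP / (TP + FP).
#' Metrics with a zero denominator are returned as NaN with the
#' `undefined` attribute naming them.
#'
#' @param cm list or named vector with non-negative counts `TP`, `TN`,
#'   `FP`, `FN`.
#' @return Named numeric vector `ACC`, `SN`, `FPR`, `PREC`.
#' @export
confusion_metrics <- function(cm) {
  TP <- cm[["TP"]]; TN <- cm[["TN"]]; FP <- cm[["FP"]]; FN <- cm[["FN"]]
  if (any(c(TP, TN, FP, FN) < 0)) stop("confusion-matrix counts must be >= 0")
  safe <- function(num, den) if (den == 0) NaN else num / den
  out <- c(ACC = safe(TP + TN, TP + TN + FP + FN),
           SN = safe(TP, TP + FN),
           FPR = safe(FP, FP + TN),
           PREC = safe(TP, TP + FP))
  und <- names(out)[is.nan(out)]
  if (length(und)) attr(out, "undefined") <- und
  out
}

#' Gini index of a score against binary labels
#'
#' Twice the area between the ROC curve and its diagonal, `2 * AUC - 1`,
#' computed from the ranked scores with the mid-rank convention for ties.
#'
#' @param scores numeric classifier scores (higher = more positive).
#' @param labels logical (or 0/1) class labels.
#' @return Gini value; 1 for perfect separation, ~0 for independence.
#' @export
gini_index <- function(scores, labels) {
  labels <- as.logical(labels)
  if (length(scores) != length(labels)) stop("scores and labels differ in length")
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  r <- rank(scores, ties.method = "average")
  auc <- (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  2 * auc - 1
}

#' Fit a single decision-tree threshold on a score
#'
#' The single-split decision tree used to calibrate Patterson peak-height
#' thresholds: cases are divided randomly into 75 percent training and 25
#' percent test; every midpoint between consecutive sorted unique training
#' scores is evaluated and the split minimizing the weighted Gini impurity
#' is chosen; the held-out confusion matrix and metrics are reported.
#' With a single free parameter no cross-validation is needed.
#'
#' @param cases data frame with a numeric score column and a logical
#'   `label` column.
#' @param score name of the score column (default `"height_pct"`).
#' @param split training fraction (default 0.75).
#' @param seed integer seed for the random split (required, for
#'   reproducibility).
#' @return List with `threshold`, `train_gini_impurity`, `cm` (held-out
#'   confusion counts), `metrics` (held-out [confusion_metrics()]), and
#'   the index vectors `train`, `test`.
#' @export
fit_threshold <- function(cases, score = "height_pct", split = 0.75, seed) {
  if (missing(seed)) stop("a seed is required for the random split")
  if (nrow(cases) < 40) stop("need at least 40 cases")
  lab <- as.logical(cases$label)
  if (sum(lab) == 0 || sum(!lab) == 0) stop("both classes must be present")
  s <- cases[[score]]
  set.seed(stream_seed(seed, "split"))
  idx <- sample(nrow(cases))
  ntr <- floor(split * nrow(cases))
  train <- idx[seq_len(ntr)]; test <- idx[-seq_len(ntr)]
  if (length(unique(lab[train])) < 2 || length(unique(lab[test])) < 2)
    stop("degenerate class balance in the random split")

  st <- s[train]; lt <- lab[train]
  u <- sort(unique(st))
  if (length(u) < 2) stop("training scores are constant")
  cand <- (u[-1] + u[-length(u)]) / 2
  imp <- vapply(cand, function(thr) {
    right <- st >= thr
    gini_node <- function(y) {
      if (!length(y)) return(0)
      p <- mean(y); 2 * p * (1 - p)
    }
    (sum(right) * gini_node(lt[right]) + sum(!right) * gini_node(lt[!right])) /
      length(st)
  }, 0)
  thr <- cand[which.min(imp)]

  pred <- s[test] >= thr
  cm <- c(TP = sum(pred & lab[test]), TN = sum(!pred & !lab[test]),
          FP = sum(pred & !lab[test]), FN = sum(!pred & lab[test]))
  list(threshold = thr, train_gini_impurity = min(imp), cm = cm,
       metrics = confusion_metrics(cm), train = train, test = test)
}

#' Simulate a labelled detection cohort
#'
#' Generates a cohort of synthetic crystals (a configurable prevalence
#' with TNCS of order 2, jitter drawn uniformly, the rest without TNCS),
#' runs the Patterson analysis on each, and records the top non-origin
#' peak height, its Z-score and the coordinate-space label - the material
#' for threshold fitting and the peak-height versus modulation scatter.
#'
#' @param n_cases cohort size.
#' @param prevalence fraction of cases with planted TNCS (default 0.1).
#' @param rmsd_range range the TNCS r.m.s.d. is drawn from, Angstrom
#'   (default 0 to 1.5; the per-copy jitter is rmsd / sqrt(2)).
#' @param seed integer seed.
#' @param cell a [unit_cell()] used for every case.
#' @param n_atoms atoms per copy.
#' @param wedge_fraction optional missing-wedge fraction applied to every
#'   case's data (default 0, complete data).
#' @param refine logical; refine the modulation statistic sigma_1^2 per
#'   case (slower).  When FALSE, `sigma1sq` is NA.
#' @param config a [tncs_config()].
#' @return Data frame with columns `case`, `tncs_planted`, `rmsd`,
#'   `height_pct` (top non-origin peak, 0 when none), `zscore`, `label`
#'   (coordinate-space classifier) and `sigma1sq` (refined modulation
#'   statistic).
#' @export
simulate_cohort <- function(n_cases = 50, prevalence = 0.1,
                            rmsd_range = c(0, 1.5), seed = 1,
                            cell = unit_cell(60, 70, 50), n_atoms = 40,
                            wedge_fraction = 0, refine = FALSE,
                            config = tncs_config()) {
  p1 <- space_group("P1")
  set.seed(stream_seed(seed, "coords"))
  planted <- stats::runif(n_cases) < prevalence
  rmsd <- stats::runif(n_cases, rmsd_range[1], rmsd_range[2])
  tvecs <- list(c(0, 0.5, 0), c(0.5, 0, 0), c(0, 0, 0.5), c(0.5, 0.5, 0))
  tpick <- sample(length(tvecs), n_cases, replace = TRUE)
  out <- vector("list", n_cases)
  for (k in seq_len(n_cases)) {
    cseed <- (seed * 131071 + k * 37) %% 2000000011
    cry <- if (planted[k])
      generate_crystal(cell, p1, n_atoms = n_atoms, n = 2, t = tvecs[[tpick[k]]],
                       jitter = rmsd[k] / sqrt(2), seed = cseed)
    else
      generate_crystal(cell, p1, n_atoms = 2 * n_atoms, n = 1, seed = cseed)
    rs <- recover_intensities(direct_sf(cry, config$pmin, config$pmax))
    if (wedge_fraction > 0) rs <- degrade(rs, wedge_fraction, seed = cseed)
    map <- compute_patterson(rs, config$pmin, config$pmax)
    pk <- pick_peaks(map, min_dist = config$origin_dist, min_height_pct = 0.1)
    lab <- pdb_tncs(crystal_to_model(cry), r_deg = config$r_deg)$has_tncs
    fit <- if (!refine) NULL else tryCatch({
      hyp0 <- tncs_hypothesis(2, if (nrow(pk)) as.numeric(pk[1, c("u", "v", "w")])
                              else tvecs[[tpick[k]]])
      refine_tncs(rs, hyp0, config$pmin, config$pmax)
    }, error = function(e) NULL)
    out[[k]] <- data.frame(
      case = k, tncs_planted = planted[k], rmsd = ifelse(planted[k], rmsd[k], NA),
      height_pct = if (nrow(pk)) pk$height_pct[1] else 0,
      zscore = if (nrow(pk)) pk$zscore[1] else 0,
      label = lab,
      sigma1sq = if (is.null(fit)) NA_real_ else fit$sigma1sq)
  }
  do.call(rbind, out)
}

#' Cohort plots: peak-height histogram and modulation scatter
#'
#' Histogram of top peak heights by label, and the scatter of the refined
#' modulation statistic sigma_1^2 against the top Patterson peak height.
#' Requires ggplot2.
#'
#' @param cohort a [simulate_cohort()] data frame.
#' @param path_prefix file prefix; writes `<prefix>_hist.pdf` and
#'   `<prefix>_scatter.pdf`.
#' @return Invisibly, the two file paths.
#' @export
cohort_plots <- function(cohort, path_prefix) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for cohort plots")
  g1 <- ggplot2::ggplot(cohort, ggplot2::aes(x = height_pct, fill = label)) +
    ggplot2::geom_histogram(bins = 30, alpha = 0.7, position = "identity") +
    ggplot2::labs(x = "top non-origin peak (% of origin)", y = "cases")
  g2 <- ggplot2::ggplot(cohort[!is.na(cohort$sigma1sq), ],
                        ggplot2::aes(x = height_pct, y = sigma1sq, colour = label)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "top non-origin peak (% of origin)",
                  y = expression(sigma[1]^2))
  f1 <- paste0(path_prefix, "_hist.pdf"); f2 <- paste0(path_prefix, "_scatter.pdf")
  ggplot2::ggsave(f1, g1, width = 6, height = 4)
  ggplot2::ggsave(f2, g2, width = 6, height = 4)
  invisible(c(f1, f2))
}
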