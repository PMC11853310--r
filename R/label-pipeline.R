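#' Aggregate feature records by 7-mer with per-position sample balancing
#'
#' Groups per-base feature records by their centered 7-mer across all
#' reference positions, balancing the number of reads between the two
#' samples at every contributing position: each sample is downsampled
#' (seeded, without replacement) to
#' `min(control_n, treated_n, max_reads_per_position)`. Positions where one
#' sample has no reads are dropped and counted.
#'
#' @param records Feature tibble with both `control` and `treated` rows (as
#'   from [read_feature_table()] or [simulate_feature_dataset()]).
#' @param max_reads_per_position Per-sample read cap at each position.
#' @param seed Integer seed for the downsampling.
#' @return The balanced records tibble (same columns), with attribute
#'   `"report"`: a tibble of per-position input/retained counts including
#'   dropped positions (`retained = 0`).
#' @export
aggregate_by_kmer <- function(records, max_reads_per_position = 50L,
                              seed = 1L) {
  check_columns(records, c(id_columns()), "feature records")
  present <- unique(records$sample)
  missing <- setdiff(c("control", "treated"), present)
  if (length(missing) > 0) {
    abort(sprintf("records contain no '%s' sample", missing[1]))
  }
  counts <- records %>%
    count(.data$kmer, .data$ref_id, .data$pos, .data$sample) %>%
    tidyr::pivot_wider(names_from = "sample", values_from = "n",
                       values_fill = 0L) %>%
    mutate(retained = pmin(.data$control, .data$treated,
                           as.integer(max_reads_per_position)))
  keep <- counts %>% filter(.data$retained >= 1L)
  balanced <- records %>%
    inner_join(keep %>% select("kmer", "ref_id", "pos", "retained"),
               by = c("kmer", "ref_id", "pos")) %>%
    group_by(.data$kmer, .data$ref_id, .data$pos, .data$sample) %>%
    group_modify(function(df, key) {
      m <- df$retained[1]
      if (nrow(df) > m) {
        s <- derive_seed(seed, paste(key$kmer, key$ref_id, key$pos, key$sample))
        df <- with_seed(s, df[sample(nrow(df), m), , drop = FALSE])
      }
      df
    }) %>%
    ungroup() %>%
    select(-"retained") %>%
    select(all_of(names(records))) %>%
    arrange(.data$kmer, .data$ref_id, .data$pos, .data$sample, .data$read_id)
  attr(balanced, "report") <- counts
  balanced
}

#' Rank features by how well they separate the two samples
#'
#' Orders features by the mean per-k-mer two-sample Kolmogorov-Smirnov
#' statistic between control and treated reads (descending); ties are broken
#' deterministically by the fixed feature-name order of [feature_columns()].
#'
#' @param balanced Balanced feature records from [aggregate_by_kmer()].
#' @param features Candidate feature columns (default: all 9 RNA002
#'   features).
#' @param n_min Minimum reads per sample for a k-mer to contribute.
#' @return A tibble `feature`, `mean_D`, `rank`, ordered by rank.
#' @export
rank_informative_features <- function(balanced,
                                      features = feature_columns("rna002"),
                                      n_min = 30L) {
  per_kmer <- kmer_ks_table(balanced, features, n_min)
  if (nrow(per_kmer) == 0) {
    abort(sprintf("no k-mer has >= %d reads per sample", n_min))
  }
  per_kmer %>%
    group_by(.data$feature) %>%
    summarise(mean_D = mean(.data$D), .groups = "drop") %>%
    mutate(feature = factor(.data$feature, levels = features)) %>%
    arrange(dplyr::desc(.data$mean_D), .data$feature) %>%
    mutate(feature = as.character(.data$feature), rank = row_number())
}

kmer_ks_table <- function(balanced, features, n_min) {
  split(balanced, balanced$kmer) %>%
    purrr::imap(function(df, km) {
      x <- df[df$sample == "control", , drop = FALSE]
      y <- df[df$sample == "treated", , drop = FALSE]
      if (nrow(x) < n_min || nrow(y) < n_min) return(NULL)
      purrr::map_dfr(features, function(f) {
        kt <- suppressWarnings(stats::ks.test(x[[f]], y[[f]]))
        tibble(kmer = km, feature = f,
               D = unname(kt$statistic), p = max(kt$p.value, .Machine$double.xmin))
      })
    }) %>%
    bind_rows()
}

#' Select candidate modified 7-mers by two-sample KS testing
#'
#' For each 7-mer with at least `n_min` balanced reads per sample, applies a
#' two-sided two-sample Kolmogorov-Smirnov test per tested feature,
#' Benjamini-Hochberg-adjusts p-values across k-mers within each feature,
#' and selects a k-mer when any tested feature passes the adjusted
#' significance level with a KS statistic of at least `D_min`.
#'
#' @param balanced Balanced feature records from [aggregate_by_kmer()].
#' @param features Features to test; defaults to the top 2 of
#'   [rank_informative_features()].
#' @param alpha Adjusted-p significance level.
#' @param D_min Effect-size floor on the KS statistic.
#' @param n_min Minimum reads per sample per k-mer; smaller k-mers are
#'   skipped (reported in the `"skipped"` attribute), not declared
#'   unmodified.
#' @return A tibble with one row per tested k-mer x feature (`kmer`,
#'   `feature`, `D`, `p`, `p_adj`, `selected`), sorted by the k-mer's
#'   minimum adjusted p.
#' @export
ks_select_kmers <- function(balanced, features = NULL, alpha = 0.01,
                            D_min = 0.1, n_min = 30L) {
  if (is.null(features)) {
    features <- head(rank_informative_features(balanced, n_min = n_min)$feature, 2)
  }
  res <- kmer_ks_table(balanced, features, n_min)
  all_kmers <- unique(balanced$kmer)
  skipped <- setdiff(all_kmers, unique(res$kmer))
  if (nrow(res) == 0) {
    out <- tibble(kmer = character(), feature = character(), D = numeric(),
                  p = numeric(), p_adj = numeric(), selected = logical())
    attr(out, "skipped") <- skipped
    return(out)
  }
  res <- res %>%
    group_by(.data$feature) %>%
    mutate(p_adj = stats::p.adjust(.data$p, method = "BH")) %>%
    ungroup() %>%
    group_by(.data$kmer) %>%
    mutate(selected = any(.data$p_adj < alpha & .data$D >= D_min),
           min_p_adj = min(.data$p_adj)) %>%
    ungroup() %>%
    arrange(.data$min_p_adj, .data$kmer, .data$feature) %>%
    select(-"min_p_adj")
  attr(res, "skipped") <- skipped
  res
}

fit_gbt <- function(x, y, seed) {
  # gradient boosted trees: 100 trees, depth 3, learning rate 0.1
  set.seed(seed)
  dtrain <- xgboost::xgb.DMatrix(as.matrix(x), label = as.numeric(y))
  xgboost::xgb.train(
    params = list(objective = "binary:logistic", max_depth = 3, eta = 0.1,
                  nthread = 1, seed = seed),
    data = dtrain, nrounds = 100, verbose = 0)
}

predict_gbt <- function(fit, x) {
  stats::predict(fit, xgboost::xgb.DMatrix(as.matrix(x)))
}

# Semi-supervised label propagation over a symmetric KNN kernel on z-scored
# features. labels: 1/0/NA (NA = unknown). Returns propagated 0/1 labels.
propagate_labels <- function(x, labels, k = 10L, max_iter = 1000L,
                             tol = 1e-6) {
  x <- scale(as.matrix(x))
  x[is.na(x)] <- 0
  n <- nrow(x)
  k <- min(k, n - 1L)
  d <- as.matrix(stats::dist(x))
  diag(d) <- Inf
  W <- matrix(0, n, n)
  for (i in seq_len(n)) {
    nn <- order(d[i, ])[seq_len(k)]
    W[i, nn] <- 1
  }
  W <- pmax(W, t(W))                  # symmetric KNN kernel
  W <- W / pmax(rowSums(W), 1)
  f <- cbind(as.numeric(labels == 0), as.numeric(labels == 1))
  f[is.na(labels), ] <- 0.5
  clamped <- !is.na(labels)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    f_new <- W %*% f
    f_new[clamped, ] <- cbind(as.numeric(labels[clamped] == 0),
                              as.numeric(labels[clamped] == 1))
    rs <- rowSums(f_new)
    f_new <- f_new / ifelse(rs > 0, rs, 1)
    if (max(abs(f_new - f)) < tol) { f <- f_new; converged <- TRUE; break }
    f <- f_new
  }
  list(labels = as.integer(f[, 2] >= 0.5), converged = converged)
}

#' Label individual reads of one selected 7-mer as modified or unmodified
#'
#' The three-stage semi-supervised labeler. Reads of one (KS-selected) 7-mer
#' are split 50:50 into train and test partitions, stratified by sample.
#' Stage 1 trains a gradient-boosting classifier on the train partition using
#' sample of origin as a surrogate label (control = unmodified, treated =
#' modified). Stage 2 marks train reads whose stage-1 probability falls in
#' the low-confidence band `(lo, hi)` as unknown and assigns them by label
#' propagation with a KNN kernel over z-scored features; confident stage-1
#' labels are never changed. Stage 3 trains a fresh gradient-boosting
#' classifier on the relabeled train partition and predicts every test read.
#'
#' @param aggregate Balanced feature records of a single 7-mer.
#' @param features Feature columns used for classification (default: the 9
#'   RNA002 features).
#' @param split Train fraction (stratified by sample).
#' @param lo,hi Stage-1 probability band treated as low confidence.
#' @param k KNN kernel size for label propagation.
#' @param seed Pipeline seed; the k-mer's own seed is derived from it.
#' @param n_min Minimum reads per sample.
#' @return A tibble with one row per read: `read_id`, `ref_id`, `pos`,
#'   `kmer`, `sample`, `partition` (`train`/`test`), `stage` (2 for train
#'   rows, 3 for test rows), `label` (`modified`/`unmodified`),
#'   `confidence`, and `stage1_prob` for train rows. The attribute
#'   `"propagation_converged"` flags stage-2 convergence (on failure,
#'   stage-1 hard labels are kept).
#' @export
label_kmer_reads <- function(aggregate,
                             features = feature_columns("rna002"),
                             split = 0.5, lo = 0.3, hi = 0.7, k = 10L,
                             seed = 1L, n_min = 30L) {
  km <- unique(aggregate$kmer)
  if (length(km) != 1) abort("label_kmer_reads() expects records of one k-mer")
  n_c <- sum(aggregate$sample == "control")
  n_t <- sum(aggregate$sample == "treated")
  if (min(n_c, n_t) < n_min) {
    abort(sprintf("k-mer %s has %d/%d reads; >= %d per sample required",
                  km, n_c, n_t, n_min))
  }
  kseed <- derive_seed(seed, km)
  agg <- with_seed(kseed, {
    aggregate %>%
      group_by(.data$sample) %>%
      mutate(partition = ifelse(
        row_number() %in% sample(n(), floor(n() * split)), "train", "test")) %>%
      ungroup()
  })
  train <- agg %>% filter(.data$partition == "train")
  test <- agg %>% filter(.data$partition == "test")

  # Stage 1: sample of origin as surrogate label
  y1 <- as.integer(train$sample == "treated")
  fit1 <- fit_gbt(train[, features], y1, kseed)
  p1 <- predict_gbt(fit1, train[, features])

  # Stage 2: low-confidence -> unknown, then KNN-kernel label propagation
  hard <- as.integer(p1 >= 0.5)
  lab2 <- ifelse(p1 > lo & p1 < hi, NA_integer_, hard)
  converged <- TRUE
  if (any(is.na(lab2))) {
    prop <- propagate_labels(train[, features], lab2, k = k)
    if (prop$converged) {
      lab2 <- prop$labels
    } else {
      converged <- FALSE
      lab2 <- hard   # fall back to stage-1 hard labels
    }
  }

  # Stage 3: final classifier on relabeled train set, predict all test reads
  fit3 <- fit_gbt(train[, features], lab2, kseed + 1L)
  p3 <- predict_gbt(fit3, test[, features])

  out <- bind_rows(
    train %>%
      mutate(stage = 2L,
             label = ifelse(lab2 == 1, "modified", "unmodified"),
             confidence = pmax(p1, 1 - p1),
             stage1_prob = p1),
    test %>%
      mutate(stage = 3L,
             label = ifelse(p3 >= 0.5, "modified", "unmodified"),
             confidence = pmax(p3, 1 - p3),
             stage1_prob = NA_real_)
  ) %>%
    select("read_id", "ref_id", "pos", "kmer", "sample", "partition",
           "stage", "label", "confidence", "stage1_prob")
  attr(out, "propagation_converged") <- converged
  out
}

#' Label reads for every selected 7-mer
#'
#' Convenience wrapper running [label_kmer_reads()] over all k-mers flagged
#' `selected` in a [ks_select_kmers()] result.
#'
#' @param balanced Balanced feature records from [aggregate_by_kmer()].
#' @param selection Result of [ks_select_kmers()].
#' @param ... Passed to [label_kmer_reads()].
#' @return Row-bound per-read labels for all selected k-mers.
#' @export
label_selected_kmers <- function(balanced, selection, ...) {
  kmers <- unique(selection$kmer[selection$selected])
  purrr::map_dfr(kmers, function(km) {
    label_kmer_reads(balanced %>% filter(.data$kmer == km), ...)
  })
}

#' Area under the ROC curve via the rank (Mann-Whitney) statistic
#'
#' @param scores Numeric classifier scores.
#' @param labels Logical or 0/1 vector, `TRUE`/1 = positive class.
#' @return AUC in `[0, 1]` (probability a random positive outscores a random
#'   negative, ties counted half).
#' @export
rank_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0 || n0 == 0) abort("both classes must be present")
  r <- rank(scores)
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Per-7-mer supervised classifier AUC (RNA004-style evaluation)
#'
#' Evaluates how separable modified and unmodified reads are per 7-mer in
#' the 39-column RNA004 feature schema: per position, samples are balanced
#' to the lower-coverage sample, positions with fewer than `min_coverage`
#' reads per sample are skipped, only 7-mers whose central base is the sole
#' candidate base are kept (e.g. `BBBABBB` for m6A), reads are split 50:50,
#' a Random Forest is trained on the train half and the ROC AUC is computed
#' on the test half. AUC is reported oriented (>= 0.5).
#'
#' @param records RNA004-mode feature records with a `sample` column
#'   (`control` = unmodified, `treated` = modified).
#' @param features Feature columns (default: numeric RNA004 columns; k-mer
#'   identifier columns are ignored for classification).
#' @param split Train fraction.
#' @param min_coverage Minimum balanced reads per sample per position.
#' @param candidate_base Modified base; 7-mers containing it outside the
#'   center are excluded.
#' @param seed Pipeline seed.
#' @param ntree Random Forest size.
#' @return A tibble `kmer`, `n_train`, `n_test`, `auc`. The attribute
#'   `"skipped"` reports excluded k-mers and the reason.
#' @export
kmer_classifier_auc <- function(records,
                                features = NULL,
                                split = 0.5, min_coverage = 100L,
                                candidate_base = "A", seed = 1L,
                                ntree = 100L) {
  if (is.null(features)) {
    features <- setdiff(feature_columns("rna004"),
                        grep("^kmer", feature_columns("rna004"), value = TRUE))
    features <- intersect(features, names(records))
  }
  skipped <- list()
  res <- split(records, records$kmer) %>%
    purrr::imap(function(df, km) {
      flanks <- paste0(substr(km, 1, 3), substr(km, 5, 7))
      if (grepl(candidate_base, flanks, fixed = TRUE)) {
        skipped[[km]] <<- "second candidate base in 7-mer"
        return(NULL)
      }
      n_c <- sum(df$sample == "control"); n_t <- sum(df$sample == "treated")
      m <- min(n_c, n_t)
      if (m < min_coverage) {
        skipped[[km]] <<- sprintf("coverage %d < %d", m, min_coverage)
        return(NULL)
      }
      kseed <- derive_seed(seed, km)
      with_seed(kseed, {
        bal <- df %>%
          group_by(.data$sample) %>%
          slice_sample(n = m) %>%
          mutate(partition = ifelse(
            row_number() %in% sample(n(), floor(n() * split)),
            "train", "test")) %>%
          ungroup()
        train <- bal %>% filter(.data$partition == "train")
        test <- bal %>% filter(.data$partition == "test")
        y <- factor(train$sample, levels = c("control", "treated"))
        fit <- randomForest::randomForest(
          x = as.data.frame(train[, features]), y = y, ntree = ntree)
        p <- stats::predict(fit, as.data.frame(test[, features]),
                            type = "prob")[, "treated"]
        auc <- rank_auc(p, test$sample == "treated")
        tibble(kmer = km, n_train = nrow(train), n_test = nrow(test),
               auc = max(auc, 1 - auc))
      })
    }) %>%
    bind_rows()
  attr(res, "skipped") <- skipped
  res
}
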