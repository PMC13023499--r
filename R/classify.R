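#' Column-wise z-score standardization with explicit statistics rows
#'
#' Standardizes every column of `X` using the mean and standard deviation of
#' the `stats_from` row subset only.  In cross-validation the statistics rows
#' are the training fold, so held-out rows never influence the scaling; for
#' global clustering they are all rows.
#'
#' @param X Numeric matrix or data.frame of numeric columns.
#' @param stats_from Row indices supplying the statistics (default: all rows).
#' @return Numeric matrix with attributes `center` and `scale`.
#' @export
standardize <- function(X, stats_from = seq_len(nrow(X))) {
  X <- as.matrix(X)
  stopifnot(is.numeric(X), length(stats_from) >= 1L)
  mu <- colMeans(X[stats_from, , drop = FALSE])
  sg <- apply(X[stats_from, , drop = FALSE], 2L, stats::sd)
  bad <- which(!is.finite(sg) | sg == 0)
  if (length(bad)) {
    stop("constant column(s) in the statistics rows: ",
         paste(colnames(X)[bad], collapse = ", "))
  }
  out <- sweep(sweep(X, 2L, mu), 2L, sg, "/")
  attr(out, "center") <- mu
  attr(out, "scale") <- sg
  out
}

#' Hierarchical agglomerative clustering with a squared-Euclidean base metric
#'
#' Bottom-up merging from singletons on the pairwise squared-Euclidean
#' distance matrix with single, complete, or average linkage, cut into the
#' `n_clusters` *main* clusters.  (The merging itself is `stats::hclust`;
#' this wrapper fixes the metric, the cut, and the result contract.)
#'
#' A plain `cutree(hc, 2)` on continuous physiological features routinely
#' splits off a handful of extreme windows instead of the two dominant
#' groups, because single/complete/average linkage trees often attach
#' outlying fragments at the top.  When `min_share > 0` (default 0.1) the
#' tree is therefore cut at increasing depth until `n_clusters` clusters
#' each hold at least `min_share` of the rows — the main clusters — and any
#' remaining minor fragment is assigned to the main cluster with the nearest
#' centroid.  With well-separated groups of comparable size this reduces
#' exactly to the plain cut; `min_share = 0` disables it.
#'
#' @param X Numeric matrix or data.frame (rows = observations).
#' @param linkage `"average"` (default), `"single"`, or `"complete"`.
#' @param n_clusters Number of main clusters (default 2).
#' @param min_share Minimum fraction of rows for a cluster to count as a
#'   main cluster (default 0.1).
#' @return Object of class `clustering_result`: list with `labels` (cluster
#'   index per row, in `1:n_clusters`), `merge` and `heights` (the merge
#'   tree; heights are non-decreasing for these linkages), `linkage`,
#'   `n_clusters`, `cut_k` (the tree depth actually used), and the
#'   underlying `hclust` object.
#' @export
agglomerative_cluster <- function(X, linkage = c("average", "single", "complete"),
                                  n_clusters = 2L, min_share = 0.1) {
  linkage <- match.arg(linkage)
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < n_clusters) stop("fewer rows than requested clusters")
  d <- stats::dist(X)^2
  hc <- stats::hclust(d, method = linkage)
  labels <- NULL
  cut_k <- n_clusters
  for (k in seq.int(n_clusters, max(n_clusters, n - 1L))) {
    labs <- stats::cutree(hc, k = k)
    sizes <- tabulate(labs, k)
    mains <- which(sizes >= max(min_share * n, 1))
    if (length(mains) >= n_clusters || min_share == 0) {
      mains <- mains[order(sizes[mains], decreasing = TRUE)][seq_len(n_clusters)]
      centroids <- matrix(vapply(mains, function(cl) {
        colMeans(X[labs == cl, , drop = FALSE])
      }, numeric(ncol(X))), nrow = ncol(X))
      labels <- integer(n)
      for (cl in seq_len(k)) {
        rows <- which(labs == cl)
        if (!length(rows)) next
        if (cl %in% mains) {
          labels[rows] <- match(cl, mains)
        } else {
          # minor fragment: nearest main-cluster centroid
          cen <- colMeans(X[rows, , drop = FALSE])
          dd <- colSums((centroids - cen)^2)
          labels[rows] <- which.min(dd)
        }
      }
      cut_k <- k
      break
    }
  }
  if (is.null(labels)) labels <- stats::cutree(hc, k = n_clusters)
  structure(
    list(labels = labels, merge = hc$merge, heights = hc$height,
         linkage = linkage, n_clusters = as.integer(n_clusters),
         cut_k = as.integer(cut_k), hclust = hc),
    class = "clustering_result"
  )
}

#' @export
print.clustering_result <- function(x, ...) {
  cat(sprintf("Agglomerative clustering (%s linkage): %d rows -> %d clusters (sizes %s)\n",
              x$linkage, length(x$labels), x$n_clusters,
              paste(tabulate(x$labels, x$n_clusters), collapse = "/")))
  invisible(x)
}

#' Name two clusters by their mean FAA
#'
#' Assigns "Class 1" to the cluster with the higher mean normalized-ratio FAA
#' (approach-related, positive-FAA side) and "Class 2" to the other.  FAA is
#' used for *naming only*: the clustering itself never sees any FAA column.
#' Equal means fall back deterministically to cluster 1 as Class 1 (with a
#' message).
#'
#' @param clustering A `clustering_result` with two clusters (or an integer
#'   label vector with two distinct values).
#' @param p_faa Per-row normalized-ratio FAA values.
#' @return Integer vector of classes (1 or 2) per row.
#' @export
label_clusters_by_faa <- function(clustering, p_faa) {
  labels <- if (inherits(clustering, "clustering_result")) clustering$labels else clustering
  stopifnot(length(labels) == length(p_faa))
  cl <- sort(unique(labels))
  if (length(cl) != 2L) stop("exactly two clusters are required")
  m <- vapply(cl, function(k) mean(p_faa[labels == k]), numeric(1L))
  if (m[1L] == m[2L]) {
    message("equal cluster FAA means; assigning Class 1 to the first cluster")
    hi <- cl[1L]
  } else {
    hi <- cl[which.max(m)]
  }
  ifelse(labels == hi, 1L, 2L)
}

#' Coincidence between predicted classes and the FAA sign
#'
#' Class 1 coincidence is the percentage of Class-1 rows with positive
#' normalized-ratio FAA; Class 2 coincidence the percentage of Class-2 rows
#' with non-positive FAA (zero counts with Class 2).  An empty class is
#' reported as `NA`.
#'
#' @param predicted Integer class labels (1 or 2) per row.
#' @param p_faa Per-row normalized-ratio FAA values.
#' @return Named numeric vector `c(class1_pct, class2_pct)` in \[0, 100\].
#' @export
coincidence_rate <- function(predicted, p_faa) {
  stopifnot(length(predicted) == length(p_faa))
  c1 <- predicted == 1L
  c2 <- predicted == 2L
  c(class1_pct = if (any(c1)) 100 * mean(p_faa[c1] > 0) else NA_real_,
    class2_pct = if (any(c2)) 100 * mean(p_faa[c2] <= 0) else NA_real_)
}

assert_no_faa_features <- function(features) {
  leak <- intersect(features, c(TARGET_COLS, "latent_faa"))
  if (length(leak)) {
    stop("FAA columns may not enter clustering/classification features: ",
         paste(leak, collapse = ", "))
  }
  invisible(features)
}

#' Fit the cluster-labelled SVM emotion model on a training set
#'
#' Standardizes the selected features over the training rows, derives
#' two-cluster labels by agglomerative clustering of the standardized
#' training features (FAA never enters the clustering), names the clusters by
#' mean training FAA, and trains an RBF-kernel SVM on the resulting classes.
#'
#' @param train Feature-table rows used for training.
#' @param features Selected feature columns (must not contain FAA columns).
#' @param linkage Clustering linkage (default `"average"`).
#' @param cost SVM cost parameter (default 1).
#' @param gamma RBF kernel width; default `1 / (n_features * mean column
#'   variance)` of the standardized training matrix.
#' @return Object of class `emotion_model`: list with the fitted `svm`,
#'   scaling statistics, features, and the training class labels.
#' @export
fit_emotion_model <- function(train, features, linkage = "average",
                              cost = 1, gamma = NULL) {
  assert_no_faa_features(features)
  Xs <- standardize(train[, features, drop = FALSE])
  cl <- agglomerative_cluster(Xs, linkage = linkage, n_clusters = 2L)
  classes <- label_clusters_by_faa(cl, train$P_Asym)
  if (is.null(gamma)) {
    gamma <- 1 / (length(features) * mean(apply(Xs, 2L, stats::var)))
  }
  fit <- e1071::svm(x = Xs, y = factor(classes, levels = c(1L, 2L)),
                    kernel = "radial", cost = cost, gamma = gamma,
                    scale = FALSE)
  structure(
    list(svm = fit, center = attr(Xs, "center"), scale = attr(Xs, "scale"),
         features = features, train_classes = classes, linkage = linkage),
    class = "emotion_model"
  )
}

#' Predict emotional-state classes for new windows
#'
#' @param object An `emotion_model` from [fit_emotion_model()].
#' @param newdata Feature-table rows to classify.
#' @param ... Unused.
#' @return Integer vector of predicted classes (1 or 2).
#' @export
predict.emotion_model <- function(object, newdata, ...) {
  X <- as.matrix(newdata[, object$features, drop = FALSE])
  Xs <- sweep(sweep(X, 2L, object$center), 2L, object$scale, "/")
  as.integer(as.character(stats::predict(object$svm, Xs)))
}

#' Leave-one-trial-out cross-validation of the emotion classifier
#'
#' For each task and each validation trial: train the standardizer, the
#' per-fold clustering labels, and the SVM on the remaining trials
#' ([fit_emotion_model()]), predict every window of the held-out trial, and
#' score the coincidence of predicted Class 1 with positive normalized-ratio
#' FAA and Class 2 with non-positive FAA.  Held-out rows never influence
#' standardization statistics, cluster labels, or the SVM fit.
#'
#' Models are fitted per participant by default: skin-conductance baselines
#' and reactivity are idiosyncratic, so pooling participants turns the
#' within-person two-state feature structure into a cross-person continuum
#' that a two-cluster cut cannot split by affect.  The held-out windows of
#' all participants are pooled per validation trial before scoring, so the
#' report keeps one row per (task, validation trial).
#'
#' @param table Feature table from [build_feature_table()].
#' @param features Selected feature columns (no FAA columns allowed).
#' @param linkage,cost,gamma Passed to [fit_emotion_model()].
#' @param labeling `"per-fold"` (default; cluster labels derived inside each
#'   training fold) or `"global"` (labels from clustering all of a
#'   participant's windows once; kept for comparison, leaks label
#'   information across folds).
#' @param per_participant Fit one model per participant (default) or one
#'   pooled model per task.
#' @return Object of class `cv_report`: list with `per_trial` (data.frame
#'   `task`, `validation_trial`, `class1_pct`, `class2_pct`), `averages`
#'   (per-task means over folds), and `overall` (grand mean of all per-fold
#'   per-class rates, in %).
#' @export
loto_cv <- function(table, features, linkage = "average", cost = 1,
                    gamma = NULL, labeling = c("per-fold", "global"),
                    per_participant = TRUE) {
  labeling <- match.arg(labeling)
  assert_no_faa_features(features)
  stopifnot(all(features %in% names(table)))
  fit_one <- function(train, global_classes = NULL) {
    if (is.null(global_classes)) {
      return(fit_emotion_model(train, features, linkage, cost, gamma))
    }
    Xs <- standardize(train[, features, drop = FALSE])
    g <- if (is.null(gamma)) {
      1 / (length(features) * mean(apply(Xs, 2L, stats::var)))
    } else gamma
    sv <- e1071::svm(x = Xs, y = factor(global_classes, levels = c(1L, 2L)),
                     kernel = "radial", cost = cost, gamma = g, scale = FALSE)
    structure(list(svm = sv, center = attr(Xs, "center"),
                   scale = attr(Xs, "scale"), features = features),
              class = "emotion_model")
  }
  per <- list()
  for (task in unique(table$task)) {
    tt <- table[table$task == task, , drop = FALSE]
    trials <- sort(unique(tt$trial))
    if (length(trials) < 2L) stop(sprintf("task %s has fewer than 2 trials", task))
    groups <- if (per_participant) {
      split(seq_len(nrow(tt)), tt$participant)
    } else {
      list(seq_len(nrow(tt)))
    }
    global_classes <- NULL
    if (labeling == "global") {
      global_classes <- integer(nrow(tt))
      for (idx in groups) {
        Xs <- standardize(tt[idx, features, drop = FALSE])
        cl <- agglomerative_cluster(Xs, linkage = linkage, n_clusters = 2L)
        global_classes[idx] <- label_clusters_by_faa(cl, tt$P_Asym[idx])
      }
    }
    for (tr in trials) {
      pred <- integer(0)
      p_faa <- numeric(0)
      for (idx in groups) {
        gt <- tt[idx, , drop = FALSE]
        train_sel <- gt$trial != tr
        if (!any(train_sel) || all(train_sel)) next
        fit <- fit_one(gt[train_sel, , drop = FALSE],
                       if (is.null(global_classes)) NULL else
                         global_classes[idx][train_sel])
        test <- gt[!train_sel, , drop = FALSE]
        pred <- c(pred, predict(fit, test))
        p_faa <- c(p_faa, test$P_Asym)
      }
      if (!length(pred)) stop(sprintf("task %s: no test rows for trial %s", task, tr))
      cc <- coincidence_rate(pred, p_faa)
      per[[length(per) + 1L]] <- data.frame(
        task = task, validation_trial = tr,
        class1_pct = cc[["class1_pct"]], class2_pct = cc[["class2_pct"]])
    }
  }
  per_trial <- do.call(rbind, per)
  averages <- do.call(rbind, lapply(split(per_trial, per_trial$task), function(d) {
    data.frame(task = d$task[1L],
               class1_pct = mean(d$class1_pct, na.rm = TRUE),
               class2_pct = mean(d$class2_pct, na.rm = TRUE))
  }))
  rownames(averages) <- NULL
  overall <- mean(c(per_trial$class1_pct, per_trial$class2_pct), na.rm = TRUE)
  structure(list(per_trial = per_trial, averages = averages, overall = overall),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat("Leave-one-trial-out CV: coincidence with the FAA sign (%)\n")
  print(x$per_trial, row.names = FALSE, digits = 4)
  cat("\nTask averages:\n")
  print(x$averages, row.names = FALSE, digits = 4)
  cat(sprintf("\nOverall average: %.1f%%\n", x$overall))
  invisible(x)
}

#' Run the full EDA-FAA analysis pipeline on a session
#'
#' Feature extraction ([build_feature_table()]), mutual-information feature
#' ranking against the chosen FAA variant ([mi_feature_ranking()]), top-k
#' selection, and leave-one-trial-out SVM validation with per-fold clustering
#' labels ([loto_cv()]).
#'
#' @param session A `synthetic_session`.
#' @param target FAA variant for the ranking (default `"P_Asym"`).
#' @param top_k Number of features kept (default 6).
#' @param group_by Grouping for the MI averaging; default
#'   `c("participant", "task")`, suitable for short synthetic trials (see
#'   [mi_feature_ranking()]).
#' @param linkage,cost,gamma Classifier parameters, see [loto_cv()].
#' @param ... Passed to [build_feature_table()].
#' @return List with `table`, `ranking`, `selected`, and `cv` (a
#'   `cv_report`).
#' @export
emotion_pipeline <- function(session, target = "P_Asym", top_k = 6L,
                             group_by = c("participant", "task"),
                             linkage = "average", cost = 1, gamma = NULL, ...) {
  table <- build_feature_table(session, ...)
  ranking <- mi_feature_ranking(table, target = target, group_by = group_by)
  selected <- select_top_features(ranking, top_k)
  cv <- loto_cv(table, selected, linkage = linkage, cost = cost, gamma = gamma)
  list(table = table, ranking = ranking, selected = selected, cv = cv)
}
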