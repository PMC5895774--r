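# Profile-matching classifier.  A query feature vector is compared against a
# labeled reference database by cosine similarity; per-class likelihoods come
# from the top-K most similar references of each class and are combined with
# a prior and a per-class multiplicative correction factor into a normalized
# Bayes posterior.  Ratio-mode features are the natural logs of the pairwise
# ratios, so that a ratio and its reciprocal contribute symmetrically and
# the "angular difference" between subjects depends only on concentration
# ratios, never on overall abundance.

#' Classifier configuration
#'
#' @param k Neighbors per class whose similarities are averaged into the
#'   class likelihood (default 5; fewer are used when a class is smaller).
#' @param priors `"uniform"` (default), `"frequency"` (class frequencies of
#'   the database), or a named numeric vector over class labels.  Uniform
#'   priors keep an imbalanced reference cohort from dominating.
#' @param correction_rate Learning rate of the iterative correction-factor
#'   update (dimensionless, default 0.01).
#' @param correction_clip Length-2 numeric range the correction factors are
#'   clipped to (default `c(0.5, 2)`).
#' @param bands Length-2 numeric `(low, high)` for [band_classify()]
#'   (default `c(10, 30)`, inside the empty gaps of the clinical fixture's
#'   coefficient bands).
#' @param include_total Include the virtual total-concentration entry of
#'   percent vectors in similarity scoring (default FALSE: the total breaks
#'   the compositional intent).
#' @param center Center features on the reference database's mean feature
#'   vector before the cosine.  Log-ratio coordinates carry large
#'   class-invariant offsets (e.g. every subject's aldosterone/DHEAS ratio
#'   is tiny) that compress all pairwise cosines toward 1; centering
#'   removes the shared offset so the angle reflects between-subject
#'   variation.  The default `NULL` centers in ratio mode and leaves the
#'   classical percent-spectrum match uncentered, as spectral library
#'   matching conventionally is.
#' @param weight_normalize Weight-normalize panels before vector building
#'   (default TRUE).
#' @param n_rematch Number of re-matchings averaged into the discriminating
#'   coefficient; values > 1 resample the database with replacement and
#'   require a seed.
#' @param seed Integer seed for the optional re-matching; ignored when
#'   `n_rematch = 1` (the classifier itself is deterministic).
#' @return List of class `classifier_config`.
#' @export
classifier_config <- function(k = 5, priors = "uniform",
                              correction_rate = 0.01,
                              correction_clip = c(0.5, 2),
                              bands = c(10, 30),
                              include_total = FALSE,
                              center = NULL,
                              weight_normalize = TRUE,
                              n_rematch = 1, seed = NULL) {
  stopifnot(k >= 1, length(correction_clip) == 2,
            correction_clip[1] > 0, correction_clip[1] <= 1,
            correction_clip[2] >= 1,
            length(bands) == 2, bands[1] < bands[2], n_rematch >= 1)
  if (n_rematch > 1 && is.null(seed))
    stop("n_rematch > 1 requires an explicit seed", call. = FALSE)
  structure(list(k = as.integer(k), priors = priors,
                 correction_rate = correction_rate,
                 correction_clip = correction_clip, bands = bands,
                 include_total = include_total, center = center,
                 weight_normalize = weight_normalize,
                 n_rematch = as.integer(n_rematch), seed = seed),
            class = "classifier_config")
}

# Tolerant cosine used inside classification: a centered feature vector can
# legitimately collapse onto the database mean; a direction-free vector is
# scored as uninformative (0.5) instead of erroring.
.sim01 <- function(a, b) {
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) return(0.5)
  (1 + min(1, max(-1, sum(a * b) / (na * nb)))) / 2
}

# Feature extraction: the numeric vector actually compared by similarity().
.features <- function(v, include_total = FALSE) {
  if (inherits(v, "ratio_vector")) {
    log(v$r)
  } else if (inherits(v, "concentration_vector")) {
    if (include_total) c(v$cn, v$cv) else v$cn
  } else if (is.numeric(v)) {
    as.numeric(v)
  } else stop("unsupported feature vector", call. = FALSE)
}

#' Similarity between two feature vectors
#'
#' Cosine similarity mapped onto `[0, 1]` by `(1 + cos theta) / 2`.
#' Ratio vectors are compared on the elementwise natural log of their
#' entries, so two panels differing only by a global scale factor score
#' exactly 1.
#'
#' @param a,b Feature vectors of the same mode and dimensionality
#'   (`ratio_vector`, `concentration_vector`, or plain numeric).
#' @param include_total For percent vectors, include the virtual total
#'   entry (default FALSE).
#' @return Similarity score in `[0, 1]`; 1 iff the feature vectors are
#'   positively proportional.
#' @export
similarity <- function(a, b, include_total = FALSE) {
  if (inherits(a, "ratio_vector") != inherits(b, "ratio_vector"))
    stop("cannot compare vectors of different modes", call. = FALSE)
  fa <- .features(a, include_total)
  fb <- .features(b, include_total)
  if (length(fa) != length(fb))
    stop("dimension mismatch: ", length(fa), " vs ", length(fb), call. = FALSE)
  if (!all(is.finite(fa)) || !all(is.finite(fb)))
    stop("non-finite feature entries", call. = FALSE)
  na <- sqrt(sum(fa^2)); nb <- sqrt(sum(fb^2))
  if (na == 0 || nb == 0)
    stop("zero-norm feature vector has no direction", call. = FALSE)
  ct <- sum(fa * fb) / (na * nb)
  (1 + min(1, max(-1, ct))) / 2
}

#' Build a labeled reference database
#'
#' @param vectors List of feature vectors, all of the same mode.
#' @param labels Class label per vector.
#' @param ids Optional subject ids (used to forbid identity matches).
#' @param mode `"ratio"` or `"absolute"`.
#' @return Object of class `reference_db`.
#' @export
reference_db <- function(vectors, labels,
                         ids = paste0("ref", seq_along(vectors)),
                         mode = c("ratio", "absolute")) {
  mode <- match.arg(mode)
  if (length(vectors) == 0) stop("empty reference database", call. = FALSE)
  stopifnot(length(vectors) == length(labels), length(ids) == length(vectors))
  want <- if (mode == "ratio") "ratio_vector" else "concentration_vector"
  ok <- vapply(vectors, function(v) inherits(v, want) || is.numeric(v), TRUE)
  if (!all(ok)) stop("mode-inhomogeneous reference database", call. = FALSE)
  structure(list(vectors = vectors, labels = as.character(labels),
                 ids = as.character(ids), mode = mode),
            class = "reference_db")
}

.resolve_priors <- function(priors, labels) {
  cls <- sort(unique(labels))
  p <- if (identical(priors, "uniform")) {
    stats::setNames(rep(1 / length(cls), length(cls)), cls)
  } else if (identical(priors, "frequency")) {
    tab <- table(labels); stats::setNames(as.numeric(tab) / sum(tab), names(tab))
  } else {
    if (is.null(names(priors)) || !all(cls %in% names(priors)))
      stop("named priors must cover every database class", call. = FALSE)
    priors[cls] / sum(priors[cls])
  }
  p[cls]
}

#' Classify a query profile against a reference database
#'
#' In ratio mode, feature vectors (query and references alike) are first
#' centered on the database's mean feature vector (see `center` in
#' [classifier_config()]); per-class likelihood is then the mean
#' similarity of the `k` most similar references within the class, and the
#' posterior is
#' `likelihood * prior * correction`, normalized over classes.  The
#' discriminating coefficient maps the winning posterior weight onto the
#' 1-100 scale as `1 + 99 * posterior_max` (optionally averaged over
#' seeded re-matchings on resampled databases).  Exactly tied posteriors
#' are broken by the class of the single most similar neighbor, then
#' lexicographically.
#'
#' @param query Feature vector (same mode as the database).
#' @param db A [reference_db()]; must not contain the query subject itself
#'   (pass `query_id` to enforce this).
#' @param cfg A [classifier_config()].
#' @param query_id Optional id of the query subject; an identical id in the
#'   database raises an identity-match error.
#' @param correction Optional named correction factors per class (defaults
#'   to 1 for every class).
#' @return Object of class `classification_result`: fields `id`,
#'   `predicted`, `posterior` (named, sums to 1), `coefficient` in
#'   `[1, 100]`, and `neighbors` (ids of the top-k matches per class).
#' @export
classify_profile <- function(query, db, cfg = classifier_config(),
                             query_id = NA_character_, correction = NULL) {
  stopifnot(inherits(db, "reference_db"))
  if (!is.na(query_id) && query_id %in% db$ids)
    stop("identity match forbidden: '", query_id, "' is in the database",
         call. = FALSE)
  feats <- lapply(db$vectors, .features, include_total = cfg$include_total)
  fq <- .features(query, include_total = cfg$include_total)
  if (any(lengths(feats) != length(fq)))
    stop("dimension mismatch between query and database vectors",
         call. = FALSE)
  if (!all(vapply(feats, function(f) all(is.finite(f)), TRUE)) ||
      !all(is.finite(fq)))
    stop("non-finite feature entries", call. = FALSE)
  center <- cfg$center %||% (db$mode == "ratio")
  if (isTRUE(center)) {
    mu <- colMeans(do.call(rbind, feats))
    feats <- lapply(feats, function(f) f - mu)
    fq <- fq - mu
  }
  sims <- vapply(feats, .sim01, numeric(1), b = fq)
  cls <- sort(unique(db$labels))
  if (is.null(correction)) correction <- stats::setNames(rep(1, length(cls)), cls)
  if (!all(cls %in% names(correction)))
    stop("correction factors must cover every database class", call. = FALSE)
  priors <- .resolve_priors(cfg$priors, db$labels)

  post_once <- function(sims) {
    lik <- vapply(cls, function(g) {
      s <- sort(sims[db$labels == g], decreasing = TRUE)
      mean(s[seq_len(min(cfg$k, length(s)))])
    }, numeric(1))
    raw <- lik * priors[cls] * correction[cls]
    if (sum(raw) == 0) raw <- priors[cls]
    raw / sum(raw)
  }
  posterior <- post_once(sims)

  top <- which(posterior == max(posterior))
  predicted <- if (length(top) == 1) cls[top] else {
    best_neighbor <- db$labels[which.max(sims)]
    if (best_neighbor %in% cls[top]) best_neighbor else cls[top][1]
  }

  coef_of <- function(p) 1 + 99 * max(p)
  coefficient <- coef_of(posterior)
  if (cfg$n_rematch > 1) {
    set.seed(cfg$seed)
    reps <- vapply(seq_len(cfg$n_rematch), function(b) {
      idx <- sample(length(sims), replace = TRUE)
      sub <- sims[idx]; names(sub) <- NULL
      dbl <- db$labels[idx]
      if (length(unique(dbl)) < length(cls)) return(coefficient)
      lik <- vapply(cls, function(g) {
        s <- sort(sub[dbl == g], decreasing = TRUE)
        mean(s[seq_len(min(cfg$k, length(s)))])
      }, numeric(1))
      raw <- lik * priors[cls] * correction[cls]
      coef_of(raw / sum(raw))
    }, numeric(1))
    coefficient <- mean(reps)
  }

  neighbors <- lapply(stats::setNames(cls, cls), function(g) {
    within <- which(db$labels == g)
    within <- within[order(sims[within], decreasing = TRUE)]
    db$ids[utils::head(within, cfg$k)]
  })
  structure(list(id = query_id, predicted = predicted, posterior = posterior,
                 coefficient = coefficient, neighbors = neighbors,
                 similarities = stats::setNames(sims, db$ids)),
            class = "classification_result")
}

#' Create a posterior/correction state
#'
#' @param classes Class labels the state tracks.
#' @param rate Learning rate of the multiplicative update.
#' @param clip Length-2 clip range for the correction factors.
#' @return Object of class `posterior_state` with unit corrections.
#' @export
posterior_state <- function(classes, rate = 0.01, clip = c(0.5, 2)) {
  structure(list(correction = stats::setNames(rep(1, length(classes)),
                                              sort(classes)),
                 rate = rate, clip = clip, step = 0L),
            class = "posterior_state")
}

#' Iterative correction-factor update
#'
#' One sequential step of the accuracy-driven correction: after a
#' misclassification, the factor of the under-predicted true class is
#' multiplied by `1 + rate`; after a correct classification every factor
#' decays geometrically toward 1.  Factors are always clipped to the
#' configured range, and the update is fully deterministic.  Many
#' sequential steps (the matching engine assumes on the order of 10,000)
#' let the factors settle where the classification accuracy stabilizes.
#'
#' @param state A [posterior_state()].
#' @param truth True class label of the step's subject.
#' @param predicted Predicted class label.
#' @return The updated `posterior_state` (step counter incremented).
#' @export
update_correction <- function(state, truth, predicted) {
  stopifnot(inherits(state, "posterior_state"))
  corr <- state$correction
  if (!truth %in% names(corr))
    stop("unknown class in outcome: ", truth, call. = FALSE)
  if (identical(truth, predicted)) {
    corr <- 1 + (corr - 1) * (1 - state$rate)
  } else {
    corr[truth] <- corr[truth] * (1 + state$rate)
  }
  corr <- pmin(pmax(corr, state$clip[1]), state$clip[2])
  state$correction <- corr
  state$step <- state$step + 1L
  state
}

#' Calibrate correction factors on a reference database
#'
#' Runs sequential leave-one-out classification passes over the database,
#' feeding each outcome to [update_correction()], for a fixed number of
#' steps (members are visited cyclically in database order).
#'
#' @param db A [reference_db()].
#' @param cfg A [classifier_config()].
#' @param steps Number of sequential classification steps (the engine's
#'   own operating assumption is >= 10,000; tests use far fewer).
#' @return The final `posterior_state`.
#' @export
calibrate_corrections <- function(db, cfg = classifier_config(), steps = 10000) {
  n <- length(db$vectors)
  state <- posterior_state(unique(db$labels), rate = cfg$correction_rate,
                           clip = cfg$correction_clip)
  for (s in seq_len(steps)) {
    i <- ((s - 1L) %% n) + 1L
    sub <- reference_db(db$vectors[-i], db$labels[-i], db$ids[-i], db$mode)
    if (length(unique(sub$labels)) < 2) next
    res <- classify_profile(db$vectors[[i]], sub, cfg, query_id = db$ids[i],
                            correction = state$correction)
    state <- update_correction(state, db$labels[i], res$predicted)
  }
  state
}

.cohort_vectors <- function(cohort, mode, cfg) {
  panels <- cohort_panels(cohort)
  lapply(seq_len(nrow(panels)), function(i) {
    p <- steroid_panel(panels[i, ])
    if (cfg$weight_normalize) p <- weight_normalize(p)
    if (mode == "ratio") ratio_vector(p, apply_weight_normalization = FALSE)
    else percent_vector(p)
  })
}

#' Leave-one-out cohort classification
#'
#' Each subject is removed in turn, the remaining subjects form the
#' reference database, and the held-out subject is classified.  Both
#' matching modes are supported: `"ratio"` (combinatorial concentration
#' ratios, log-cosine similarity) and `"absolute"` (percent concentration
#' vectors).
#'
#' @param cohort A [steroid_cohort()] with complete panels and class
#'   labels.
#' @param mode `"ratio"` or `"absolute"`.
#' @param cfg A [classifier_config()].
#' @param correction_steps If > 0, calibrate correction factors on each
#'   leave-one-out database for this many sequential steps before
#'   classifying (default 0: unit corrections).
#' @return Data frame with one row per subject: `id`, `truth`,
#'   `predicted`, `coefficient`, and one posterior column per class.
#' @export
loo_classify <- function(cohort, mode = c("ratio", "absolute"),
                         cfg = classifier_config(), correction_steps = 0) {
  mode <- match.arg(mode)
  if (anyNA(cohort$class))
    stop("every subject needs a class label for leave-one-out", call. = FALSE)
  if (length(unique(cohort$class)) < 2)
    stop("leave-one-out needs at least two classes", call. = FALSE)
  vecs <- .cohort_vectors(cohort, mode, cfg)
  ids <- cohort$id
  labels <- as.character(cohort$class)
  cls <- sort(unique(labels))
  rows <- lapply(seq_along(vecs), function(i) {
    db <- reference_db(vecs[-i], labels[-i], ids[-i], mode)
    corr <- NULL
    if (correction_steps > 0)
      corr <- calibrate_corrections(db, cfg, correction_steps)$correction
    res <- classify_profile(vecs[[i]], db, cfg, query_id = ids[i],
                            correction = corr)
    post <- stats::setNames(rep(0, length(cls)), cls)
    post[names(res$posterior)] <- res$posterior
    c(list(id = ids[i], truth = labels[i], predicted = res$predicted,
           coefficient = res$coefficient), as.list(post))
  })
  out <- do.call(rbind, lapply(rows, function(r) as.data.frame(r, check.names = FALSE)))
  names(out)[-(1:4)] <- paste0("p_", cls)
  rownames(out) <- NULL
  out
}

#' Coefficient band rule
#'
#' Maps a 1-100 discriminating coefficient onto a class label:
#' `coefficient >= high` is PCa, `coefficient <= low` is HC, anything in
#' between is BPH.  The defaults `(10, 30)` sit inside the empty gaps
#' between the three coefficient bands of the clinical fixture.
#'
#' @param coefficient Numeric vector of 1-100 coefficients.
#' @param bands Length-2 numeric `(low, high)`, `low < high`.
#' @return Character vector of class labels.
#' @export
#' @examples
#' band_classify(c(44.5, 22.6, 5.3))
band_classify <- function(coefficient, bands = c(10, 30)) {
  stopifnot(length(bands) == 2, bands[1] < bands[2])
  ifelse(coefficient >= bands[2], "PCa",
         ifelse(coefficient <= bands[1], "HC", "BPH"))
}

#' Write classification results as delimited text
#'
#' @param results Data frame from [loo_classify()].
#' @param path Output file.
#' @param sep Field separator.
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path, sep = ",") {
  utils::write.table(results, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}
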