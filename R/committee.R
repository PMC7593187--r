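#' Fit the ROC-gated model committee
#'
#' Trains several model families on the extreme-cell climate features of
#' labeled presence / pseudo-absence cells and gates each by its discrimination
#' on a held-out split: a member enters the ensemble only if its holdout AUC
#' exceeds `inclusion_threshold`. The default committee holds four families:
#'
#' * `glm_ridge` -- ridge-regularized linear-logistic regression (glmnet),
#' * `gam_spline` -- additive logistic model with spline smooths (mgcv),
#' * `random_forest` -- probability forest (ranger),
#' * `envelope` -- rectilinear surface-range envelope scoring 1 inside
#'   per-feature percentile bounds of the training presences, else 0.
#'
#' A single stratified split (default 70% training / 30% testing, seeded) is
#' used for every family; feature standardization parameters are fitted on the
#' training rows only.
#'
#' @param features A `feature_table` from [extract_features()].
#' @param labels data.frame `cell_id,label` from [sample_pseudo_absences()].
#' @param inclusion_threshold Holdout-AUC gate (default 0.85).
#' @param split_fraction Training fraction (default 0.70).
#' @param families Character subset of the four family names.
#' @param envelope_percentiles Lower/upper presence percentiles bounding the
#'   envelope member (default `c(0.025, 0.975)`).
#' @param seed Integer seed controlling split and stochastic learners.
#' @return Object of class `ensemble_model`: `members` (each with `family`,
#'   `fit`, `holdout_auc`, `included`), `center`/`scale`, `inclusion_threshold`,
#'   `split_fraction`, `feature_names`, `seed`.
#' @export
fit_committee <- function(features, labels,
                          inclusion_threshold = 0.85,
                          split_fraction = 0.70,
                          families = c("glm_ridge", "gam_spline",
                                       "random_forest", "envelope"),
                          envelope_percentiles = c(0.025, 0.975),
                          seed = 1L) {
  fnames <- feature_names()
  stopifnot(all(fnames %in% names(features)), all(c("cell_id", "label") %in%
                                                    names(labels)))
  df <- merge(labels, features, by = "cell_id")
  df <- df[stats::complete.cases(df[, fnames]), ]
  if (length(unique(df$label)) < 2) stop("need both classes after masking")

  rng <- local_rng(seed)
  on.exit(rng())
  # stratified split: same fraction of each class into training
  train_idx <- unlist(lapply(split(seq_len(nrow(df)), df$label), function(ix) {
    sample(ix, max(1L, round(split_fraction * length(ix))))
  }), use.names = FALSE)
  train <- df[train_idx, ]
  test <- df[-train_idx, ]
  if (length(unique(test$label)) < 2) stop("holdout split lost a class")

  ctr <- vapply(train[fnames], mean, numeric(1))
  scl <- vapply(train[fnames], stats::sd, numeric(1))
  scl[scl == 0] <- 1

  members <- lapply(families, function(fam) {
    fit <- tryCatch(
      fit_member(fam, train, fnames, ctr, scl, envelope_percentiles, seed),
      error = function(e) {
        warning("family ", fam, " failed to fit: ", conditionMessage(e))
        NULL
      })
    if (is.null(fit)) {
      return(list(family = fam, fit = NULL, holdout_auc = NA_real_,
                  included = FALSE))
    }
    auc <- roc_auc(predict_member(fit, test, fnames, ctr, scl), test$label)
    list(family = fam, fit = fit, holdout_auc = auc,
         included = auc > inclusion_threshold)
  })
  names(members) <- families
  if (!any(vapply(members, `[[`, logical(1), "included"))) {
    stop("empty ensemble: no member passed the AUC gate of ",
         inclusion_threshold)
  }
  structure(list(members = members, center = ctr, scale = scl,
                 inclusion_threshold = inclusion_threshold,
                 split_fraction = split_fraction,
                 feature_names = fnames, seed = seed),
            class = "ensemble_model")
}

fit_member <- function(family, train, fnames, ctr, scl, env_pct, seed) {
  y <- train$label
  X <- as.matrix(train[, fnames])
  Xs <- scale(X, center = ctr, scale = scl)
  switch(family,
    glm_ridge = {
      fit <- glmnet::glmnet(Xs, y, family = "binomial", alpha = 0,
                            lambda = 0.01, standardize = FALSE)
      list(kind = "glm_ridge", fit = fit)
    },
    gam_spline = {
      terms <- vapply(fnames, function(f) {
        k <- min(4L, length(unique(train[[f]])))
        if (k >= 3) sprintf("s(%s, k = %d)", f, k) else f
      }, character(1))
      fml <- stats::as.formula(paste("label ~", paste(terms, collapse = " + ")))
      fit <- mgcv::gam(fml, family = stats::binomial(), data = train,
                       method = "REML", select = TRUE)
      list(kind = "gam_spline", fit = fit)
    },
    random_forest = {
      fit <- ranger::ranger(x = train[, fnames],
                            y = factor(y, levels = c(0, 1)),
                            probability = TRUE, num.trees = 500,
                            seed = as.integer(seed))
      list(kind = "random_forest", fit = fit)
    },
    envelope = {
      pres <- train[y == 1L, fnames, drop = FALSE]
      lower <- vapply(pres, stats::quantile, numeric(1), probs = env_pct[1],
                      names = FALSE)
      upper <- vapply(pres, stats::quantile, numeric(1), probs = env_pct[2],
                      names = FALSE)
      list(kind = "envelope", lower = lower, upper = upper)
    },
    stop("unknown model family: ", family)
  )
}

predict_member <- function(member, newdata, fnames, ctr, scl) {
  X <- as.matrix(newdata[, fnames])
  switch(member$kind,
    glm_ridge = {
      Xs <- scale(X, center = ctr, scale = scl)
      as.numeric(stats::predict(member$fit, newx = Xs, type = "response"))
    },
    gam_spline = {
      as.numeric(stats::predict(member$fit, newdata = newdata,
                                type = "response"))
    },
    random_forest = {
      stats::predict(member$fit, data = newdata[, fnames])$predictions[, "1"]
    },
    envelope = {
      inside <- rep(TRUE, nrow(X))
      for (j in seq_along(fnames)) {
        inside <- inside & X[, j] >= member$lower[j] & X[, j] <= member$upper[j]
      }
      as.numeric(inside)
    },
    stop("unknown member kind")
  )
}

#' @export
print.ensemble_model <- function(x, ...) {
  cat("ensemble_model (gate AUC >", x$inclusion_threshold, ")\n")
  for (m in x$members) {
    cat(sprintf("  %-14s AUC = %s  %s\n", m$family,
                ifelse(is.na(m$holdout_auc), "failed",
                       sprintf("%.3f", m$holdout_auc)),
                ifelse(m$included, "[included]", "[excluded]")))
  }
  invisible(x)
}

#' Re-apply the AUC inclusion gate at a different threshold
#'
#' Recomputes the `included` flags from the stored holdout AUCs without
#' refitting; errors if no member would remain.
#'
#' @param model An `ensemble_model`.
#' @param inclusion_threshold New gate.
#' @return The updated model.
#' @export
gate_members <- function(model, inclusion_threshold) {
  stopifnot(inherits(model, "ensemble_model"))
  model$members <- lapply(model$members, function(m) {
    m$included <- !is.na(m$holdout_auc) && m$holdout_auc > inclusion_threshold
    m
  })
  model$inclusion_threshold <- inclusion_threshold
  if (!any(vapply(model$members, `[[`, logical(1), "included"))) {
    stop("empty ensemble: no member passed the AUC gate of ",
         inclusion_threshold)
  }
  model
}

#' Suitability map container
#'
#' Per-coarse-cell ensemble probability with a provenance tag. `NA`
#' probabilities mark cells masked for missing climate; `ice` flags cells
#' zeroed by an ice sheet.
#'
#' @param prob Numeric vector of probabilities (one per coarse cell).
#' @param tag Provenance (time slice or scenario label).
#' @param ice Logical ice-mask flags (default all `FALSE`).
#' @return Object of class `suitability_map`.
#' @export
suitability_map <- function(prob, tag = "current", ice = rep(FALSE, length(prob))) {
  ok <- stats::na.omit(prob)
  if (any(ok < 0 | ok > 1)) stop("probabilities must be in [0, 1]")
  structure(list(prob = as.numeric(prob), ice = as.logical(ice),
                 tag = as.character(tag)),
            class = "suitability_map")
}

#' @export
print.suitability_map <- function(x, ...) {
  cat(sprintf("suitability_map [%s]: %d cells, %d masked, %d iced\n",
              x$tag, length(x$prob), sum(is.na(x$prob)), sum(x$ice)))
  invisible(x)
}

#' Ensemble suitability prediction
#'
#' Per cell, the unweighted mean of the included members' probabilities
#' (an AUC-weighted mean is available via `weight_by_auc = TRUE`). Rows with
#' missing features stay masked (`NA`).
#'
#' @param model A fitted `ensemble_model`.
#' @param features A `feature_table` with the same eight columns the model
#'   was trained on.
#' @param tag Provenance tag for the resulting map.
#' @param weight_by_auc Weight members by holdout AUC instead of equally.
#' @return A [suitability_map()] over the feature table's cells.
#' @export
predict_ensemble <- function(model, features, tag = "current",
                             weight_by_auc = FALSE) {
  stopifnot(inherits(model, "ensemble_model"))
  if (!all(model$feature_names %in% names(features))) {
    stop("feature columns do not match the trained model")
  }
  inc <- Filter(function(m) isTRUE(m$included), model$members)
  if (length(inc) == 0) stop("no included members")
  ok <- stats::complete.cases(features[, model$feature_names])
  prob <- rep(NA_real_, nrow(features))
  if (any(ok)) {
    preds <- vapply(inc, function(m) {
      p <- predict_member(m$fit, features[ok, , drop = FALSE],
                          model$feature_names, model$center, model$scale)
      pmin(pmax(p, 0), 1)
    }, numeric(sum(ok)))
    preds <- matrix(preds, nrow = sum(ok))
    w <- if (weight_by_auc) {
      vapply(inc, `[[`, numeric(1), "holdout_auc")
    } else rep(1, length(inc))
    prob[ok] <- as.numeric(preds %*% (w / sum(w)))
  }
  suitability_map(prob, tag = tag)
}

#' Dump an ensemble summary as JSON
#'
#' Family names, holdout AUCs, inclusion flags, gate, split and seed (not
#' the fitted objects themselves).
#'
#' @param model An `ensemble_model`; `file` output path.
#' @export
write_ensemble_json <- function(model, file) {
  out <- list(
    inclusion_threshold = model$inclusion_threshold,
    split_fraction = model$split_fraction,
    seed = model$seed,
    members = lapply(unname(model$members), function(m) {
      list(family = m$family, holdout_auc = m$holdout_auc,
           included = m$included)
    })
  )
  jsonlite::write_json(out, file, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(file)
}
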