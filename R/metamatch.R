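# Meta-matching-style transfer stage: a bank of proxy-phenotype
# predictors trained on large source cohorts turns each target
# subject's FC vector into a row of proxy features; a final KRR on
# those proxies predicts the clinical target. The bank has two model
# families (a linear ridge and a ridge on a seeded random nonlinear
# feature expansion) and two layers: base phenotypes predicted from FC,
# extra phenotypes predicted from the base-proxy rows.

# Multi-response ridge with centering; primal or dual depending on
# whether features outnumber samples.
ridge_train <- function(X, Y, lambda = 1) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  xm <- colMeans(X); ym <- colMeans(Y)
  Xc <- sweep(X, 2, xm); Yc <- sweep(Y, 2, ym)
  d <- ncol(X); n <- nrow(X)
  B <- if (d <= n) {
    solve(crossprod(Xc) + lambda * diag(d), crossprod(Xc, Yc))
  } else {
    crossprod(Xc, solve(tcrossprod(Xc) + lambda * diag(n), Yc))
  }
  list(coef = B, x_mean = xm, y_mean = ym)
}

ridge_predict <- function(fit, X) {
  sweep(sweep(as.matrix(X), 2, fit$x_mean) %*% fit$coef, 2, fit$y_mean, `+`)
}

# Seeded random ReLU feature expansion (stand-in nonlinear family).
relu_expansion <- function(n_inputs, n_hidden, seed) {
  with_seed(seed, list(
    W = matrix(stats::rnorm(n_inputs * n_hidden, sd = 1 / sqrt(n_inputs)),
               n_inputs, n_hidden),
    b = stats::rnorm(n_hidden, sd = 0.5)))
}

relu_apply <- function(exp, X) {
  pmax(sweep(as.matrix(X) %*% exp$W, 2, exp$b, `+`), 0)
}

# Drop zero-variance phenotype columns with a warning; returns kept matrix.
drop_constant_phenotypes <- function(P, what) {
  sds <- matrixStats_colSds(as.matrix(P))
  if (any(sds == 0)) {
    nm <- colnames(P)[sds == 0]
    warning("excluding zero-variance ", what, " phenotype(s): ",
            paste(nm, collapse = ", "), "; bank dimension adjusted",
            call. = FALSE)
  }
  as.matrix(P)[, sds > 0, drop = FALSE]
}

#' Train a proxy-phenotype model bank on source cohorts
#'
#' The first source cohort supplies the base phenotypes, modelled
#' directly from FC features by each family (family `linear`: ridge
#' regression; family `nonlinear`: ridge on a seeded random ReLU
#' feature expansion, a desk-scale stand-in for a deep network). Later
#' cohorts supply extra phenotypes, modelled from the base-proxy rows
#' rather than raw FC -- the stacked, multilayer part of the scheme.
#' Phenotypes with zero variance in their source cohort are excluded
#' with a warning and the bank dimension adjusted.
#'
#' @param source_cohorts List of cohorts, each a list with `X`
#'   (subjects by edges feature matrix) and `phenotypes` (subjects by
#'   phenotypes matrix with column names). The first is the base
#'   cohort.
#' @param n_families 1 (linear only) or 2 (linear + nonlinear).
#' @param n_hidden Width of the random ReLU expansion (default 100).
#' @param ridge_lambda Ridge penalty for every bank model (default 1).
#' @param seed Seed for the random expansions (the only randomness).
#' @return Object of class `proxy_bank`; see [proxy_dim()],
#'   [generate_proxies()].
#' @export
train_proxy_bank <- function(source_cohorts, n_families = 2L,
                             n_hidden = 100L, ridge_lambda = 1, seed = 1L) {
  if (!n_families %in% 1:2) stop("n_families must be 1 or 2")
  if (length(source_cohorts) < 1) stop("need at least one source cohort")
  families <- c("linear", "nonlinear")[seq_len(n_families)]

  base <- source_cohorts[[1]]
  Xb <- as.matrix(base$X)
  Pb <- drop_constant_phenotypes(base$phenotypes, "base")
  if (ncol(Pb) == 0) stop("no usable base phenotypes")

  base_models <- list(linear = ridge_train(Xb, Pb, ridge_lambda))
  expansions <- list()
  if ("nonlinear" %in% families) {
    expansions$base <- relu_expansion(ncol(Xb), n_hidden, mix_seed(seed, 1L))
    base_models$nonlinear <- ridge_train(relu_apply(expansions$base, Xb), Pb,
                                         ridge_lambda)
  }

  bank <- structure(list(families = families, n_edges = ncol(Xb),
                         base_names = colnames(Pb),
                         base_models = base_models,
                         extra_names = character(0),
                         extra_models = NULL, expansions = expansions,
                         ridge_lambda = ridge_lambda, seed = seed),
                    class = "proxy_bank")

  extra_cohorts <- source_cohorts[-1]
  if (length(extra_cohorts)) {
    fits <- list(linear = list(), nonlinear = list())
    extra_names <- character(0)
    exp_seed <- 2L
    for (ec in extra_cohorts) {
      Pe <- drop_constant_phenotypes(ec$phenotypes, "extra")
      if (ncol(Pe) == 0) next
      proxies <- base_proxies(bank, ec$X)
      fits$linear[[length(fits$linear) + 1L]] <-
        list(names = colnames(Pe), fit = ridge_train(proxies, Pe, ridge_lambda))
      if ("nonlinear" %in% families) {
        if (is.null(bank$expansions$extra))
          bank$expansions$extra <- relu_expansion(ncol(proxies), n_hidden,
                                                  mix_seed(seed, exp_seed))
        H <- relu_apply(bank$expansions$extra, proxies)
        fits$nonlinear[[length(fits$nonlinear) + 1L]] <-
          list(names = colnames(Pe), fit = ridge_train(H, Pe, ridge_lambda))
      }
      extra_names <- c(extra_names, colnames(Pe))
    }
    bank$extra_models <- fits
    bank$extra_names <- extra_names
  }
  bank
}

# Base-layer proxy rows (n_families * n_base columns) from raw FC.
base_proxies <- function(bank, X) {
  X <- as.matrix(X)
  if (ncol(X) != bank$n_edges)
    stop("edge count (", ncol(X), ") does not match bank training (",
         bank$n_edges, ")")
  blocks <- list(linear = ridge_predict(bank$base_models$linear, X))
  if ("nonlinear" %in% bank$families)
    blocks$nonlinear <- ridge_predict(bank$base_models$nonlinear,
                                      relu_apply(bank$expansions$base, X))
  out <- do.call(cbind, blocks[bank$families])
  colnames(out) <- unlist(lapply(bank$families, function(f)
    paste0(bank$base_names, "__", f)))
  out
}

#' Proxy-feature dimension of a bank
#'
#' Always `n_families * (n_base + n_extra)` after any zero-variance
#' exclusions.
#'
#' @param bank A `proxy_bank`.
#' @return Integer column count of the proxy feature matrix.
#' @export
proxy_dim <- function(bank) {
  length(bank$families) * (length(bank$base_names) + length(bank$extra_names))
}

#' @export
print.proxy_bank <- function(x, ...) {
  cat(sprintf("<proxy_bank> %d base + %d extra phenotypes x %d families = %d proxies\n",
              length(x$base_names), length(x$extra_names),
              length(x$families), proxy_dim(x)))
  invisible(x)
}

#' Generate proxy features for target subjects
#'
#' One row per subject, one column per (phenotype, family): base
#' proxies are predicted from the FC features, extra proxies from the
#' base-proxy rows (never from raw FC).
#'
#' @param bank A [train_proxy_bank()] result.
#' @param X Subjects-by-edges feature matrix with the bank's edge
#'   ordering.
#' @return Numeric matrix, subjects by [proxy_dim()], with labelled
#'   columns `"<phenotype>__<family>"`.
#' @export
generate_proxies <- function(bank, X) {
  stopifnot(inherits(bank, "proxy_bank"))
  pb <- base_proxies(bank, X)
  if (!length(bank$extra_names)) return(pb)
  extra_blocks <- list()
  for (f in bank$families) {
    feats <- if (f == "linear") pb else relu_apply(bank$expansions$extra, pb)
    for (fit in bank$extra_models[[f]]) {
      blk <- ridge_predict(fit$fit, feats)
      colnames(blk) <- paste0(fit$names, "__", f)
      extra_blocks[[length(extra_blocks) + 1L]] <- blk
    }
  }
  cbind(pb, do.call(cbind, extra_blocks))
}

#' Predict clinical targets via the meta-matching stage
#'
#' Generates proxy features for the training and test subjects, drops
#' proxy columns that are constant in training (constant features have
#' no defined similarity under a correlation kernel), and delegates to
#' the KRR module on the proxy features. Applies to baseline-FC
#' predictors only: the bank is trained on single-visit source scans,
#' so there is nothing to transfer for longitudinal FC change.
#'
#' @param bank A `proxy_bank`.
#' @param X_train,X_test Subjects-by-edges feature matrices.
#' @param y_train Training outcomes.
#' @param lambda_grid Candidate penalties for the final KRR.
#' @param seed Seed for the KRR inner fold allocation.
#' @return Numeric vector of test predictions.
#' @export
metamatch_fit_predict <- function(bank, X_train, y_train, X_test,
                                  lambda_grid = krr_lambda_grid(), seed = 1L) {
  P_train <- generate_proxies(bank, X_train)
  P_test <- generate_proxies(bank, X_test)
  sds <- matrixStats_colSds(P_train)
  if (any(sds == 0)) {
    warning("dropping constant proxy column(s): ",
            paste(colnames(P_train)[sds == 0], collapse = ", "), call. = FALSE)
    P_train <- P_train[, sds > 0, drop = FALSE]
    P_test <- P_test[, sds > 0, drop = FALSE]
  }
  model <- krr_fit(P_train, y_train, lambda_grid = lambda_grid, seed = seed)
  predict(model, P_test)
}

#' Simulate a source cohort of FC features and phenotypes
#'
#' Produces the large, healthy-cohort training material for
#' [train_proxy_bank()]: per-subject FC feature rows from the same
#' low-rank backbone model as [generate_cohort()], and phenotypes that
#' are noisy linear functions of sparse edge sets. Supplying the
#' returned `backbone` and/or `weights` to a second call yields
#' cohorts (for example a small target cohort) drawn from the same
#' population, so that transfer is meaningful.
#'
#' @param n_subjects Cohort size.
#' @param n_regions Parcellation size.
#' @param n_phenotypes Number of phenotypes to simulate.
#' @param pheno_r2 Fraction of phenotype variance carried by the FC
#'   signal (default 0.5).
#' @param n_causal_edges Sparse support size per phenotype (default 3).
#' @param n_timepoints Samples per simulated scan (default 120).
#' @param n_latent Backbone rank (default 5).
#' @param subject_sd Subject-level loading perturbation (default 0.35).
#' @param seed Integer seed.
#' @param backbone Optional regions-by-latent loading matrix to reuse.
#' @param weights Optional edges-by-phenotypes weight matrix to reuse.
#' @return List with `X` (subjects by edges), `phenotypes` (subjects by
#'   phenotypes, named `phen01`, ...), `backbone`, `weights`, and
#'   `signal` (the noiseless phenotype signals).
#' @export
simulate_source_cohort <- function(n_subjects, n_regions, n_phenotypes,
                                   pheno_r2 = 0.5, n_causal_edges = 3L,
                                   n_timepoints = 120L, n_latent = 5L,
                                   subject_sd = 0.35, seed = 1L,
                                   backbone = NULL, weights = NULL) {
  n_edges <- n_regions * (n_regions - 1) / 2
  with_seed(seed, {
    L <- if (is.null(backbone))
      matrix(stats::rnorm(n_regions * n_latent), n_regions, n_latent)
    else backbone
    W <- if (is.null(weights)) {
      W0 <- matrix(0, n_edges, n_phenotypes)
      for (k in seq_len(n_phenotypes)) {
        idx <- sample.int(n_edges, n_causal_edges)
        W0[idx, k] <- sample(c(-1, 1), n_causal_edges, replace = TRUE)
      }
      W0
    } else weights
    X <- matrix(NA_real_, n_subjects, n_edges)
    for (s in seq_len(n_subjects)) {
      D <- L + subject_sd * matrix(stats::rnorm(n_regions * n_latent),
                                   n_regions, n_latent)
      X[s, ] <- fc_vectorize(compute_fc(simulate_scan(D, n_timepoints)))
    }
    G <- X %*% W
    Gz <- scale(G)
    phen <- sqrt(pheno_r2) * Gz +
      sqrt(1 - pheno_r2) * matrix(stats::rnorm(n_subjects * n_phenotypes),
                                  n_subjects, n_phenotypes)
    colnames(phen) <- sprintf("phen%02d", seq_len(n_phenotypes))
    list(X = X, phenotypes = phen, backbone = L, weights = W,
         signal = G)
  })
}
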