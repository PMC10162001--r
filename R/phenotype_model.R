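# The phenotype confirmation model: an L2-regularised logistic regression
# over mention vectors that decides whether a candidate mention-UMLS link
# states a real phenotype of the patient. Trained either on weakly labelled
# data (rule-derived) or on manually annotated pairs; only the provenance
# tag differs.

#' Fit the phenotype confirmation model
#'
#' L2-penalised binomial maximum-likelihood fit by Newton/IRLS: minimises
#' `sum(logloss) + ||w||^2 / (2C)` with the intercept unpenalised, where
#' `reg_strength` is the inverse regularisation strength C. The fit is
#' deterministic; the seed is recorded in `train_meta` for provenance of
#' the surrounding sampling.
#'
#' @param vectors Numeric matrix, one mention vector per row.
#' @param labels 0/1 vector, one per row; both classes must be present.
#' @param reg_strength Inverse regularisation strength C (default 1.0).
#' @param seed Integer seed recorded in `train_meta`.
#' @param max_iter Optimiser iteration cap (default 100).
#' @param tol Convergence tolerance (default 1e-4).
#' @param provenance `"weak"` (rule-labelled training data) or `"strong"`
#'   (manually labelled).
#' @param threshold Decision threshold on the confirmation probability
#'   (default 0.5).
#' @return A `confirmation_model` with `weights`, `bias`, `threshold`,
#'   `provenance`, and `train_meta`.
#' @export
fit_confirmation_model <- function(vectors, labels, reg_strength = 1.0,
                                   seed = 42L, max_iter = 100L, tol = 1e-4,
                                   provenance = c("weak", "strong"),
                                   threshold = 0.5) {
  provenance <- match.arg(provenance)
  vectors <- as.matrix(vectors)
  labels <- as.integer(labels)
  if (nrow(vectors) != length(labels)) {
    stop("dimension mismatch: ", nrow(vectors), " vectors vs ",
         length(labels), " labels")
  }
  if (nrow(vectors) < 2) stop("need at least 2 training examples")
  if (length(unique(labels)) < 2) {
    stop("training labels contain a single class; both classes are required")
  }
  if (reg_strength <= 0) stop("reg_strength must be positive")
  n <- nrow(vectors)
  fit <- ridge_logistic_irls(vectors, labels, penalty = 1 / reg_strength,
                             max_iter = max_iter, tol = tol)
  model <- list(weights = fit$weights, bias = fit$bias, threshold = threshold,
                provenance = provenance,
                train_meta = list(n = n, seed = as.integer(seed),
                                  reg_strength = reg_strength,
                                  max_iter = as.integer(max_iter), tol = tol,
                                  converged = fit$converged))
  class(model) <- "confirmation_model"
  model
}

# Newton/IRLS for the ridge-penalised binomial log-likelihood:
#   minimise  sum_i log(1 + exp(-(2 y_i - 1) (x_i w + b)))  +  penalty/2 ||w||^2
# with the intercept unpenalised. The ridge term keeps the Hessian positive
# definite, so plain Newton steps (with step-halving on the rare uphill
# step) converge; convergence is declared on the gradient max-norm.
ridge_logistic_irls <- function(X, y, penalty, max_iter = 100L, tol = 1e-4) {
  n <- nrow(X); d <- ncol(X)
  Xb <- cbind(1, X)
  beta <- numeric(d + 1L)
  pen <- c(0, rep(penalty, d))
  objective <- function(b) {
    eta <- drop(Xb %*% b)
    # numerically stable -loglik: log(1+exp(eta)) - y*eta
    sum(ifelse(eta > 30, eta, log1p(exp(eta))) - y * eta) +
      0.5 * penalty * sum(b[-1]^2)
  }
  obj <- objective(beta)
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    eta <- drop(Xb %*% beta)
    p <- stats::plogis(eta)
    grad <- drop(crossprod(Xb, p - y)) + pen * beta
    if (max(abs(grad)) < tol) { converged <- TRUE; break }
    w <- pmax(p * (1 - p), 1e-10)
    H <- crossprod(Xb * w, Xb)
    diag(H) <- diag(H) + pen
    step <- solve(H, grad)
    # step-halving safeguards the quadratic approximation far from optimum
    alpha <- 1
    repeat {
      cand <- beta - alpha * step
      cand_obj <- objective(cand)
      if (cand_obj <= obj + 1e-12 || alpha < 1e-8) break
      alpha <- alpha / 2
    }
    if (abs(obj - cand_obj) < tol * 1e-4 && max(abs(grad)) < sqrt(tol)) {
      beta <- cand; converged <- TRUE; break
    }
    beta <- cand; obj <- cand_obj
  }
  list(weights = beta[-1], bias = beta[1], converged = converged)
}

#' @export
print.confirmation_model <- function(x, ...) {
  cat("<confirmation_model> d = ", length(x$weights), ", provenance = ",
      x$provenance, ", threshold = ", x$threshold,
      ", trained on n = ", x$train_meta$n, "\n", sep = "")
  invisible(x)
}

#' Subsample labelled pairs from a weak dataset
#'
#' Uniform random sample without replacement of `min(n, |labelled|)`
#' labelled mention-UMLS pairs (positives and negatives pooled), seeded.
#'
#' @param dataset A `weak_dataset`.
#' @param n Sample size (default 9000 — beyond which additional weak pairs
#'   add little).
#' @param seed Integer seed.
#' @return List with `links` (sampled link table) and `labels` (0/1).
#' @export
subsample_training <- function(dataset, n = 9000L, seed = 42L) {
  stopifnot(inherits(dataset, "weak_dataset"))
  pool <- rbind(dataset$positive, dataset$negative)
  if (nrow(pool) == 0) {
    return(list(links = pool, labels = integer(0)))
  }
  k <- min(as.integer(n), nrow(pool))
  idx <- if (k == 0) integer(0) else
    with_preserved_seed(seed, sample.int(nrow(pool), k))
  links <- pool[idx, , drop = FALSE]
  rownames(links) <- NULL
  list(links = links, labels = links$y_weak)
}

#' Apply the confirmation model
#'
#' @param model A `confirmation_model`.
#' @param vectors Numeric matrix (or single vector) of mention vectors.
#' @return data.frame with `probability` (logistic of the linear score) and
#'   `decision` (1 when probability >= threshold; ties go to positive).
#' @export
predict_confirmation <- function(model, vectors) {
  stopifnot(inherits(model, "confirmation_model"))
  if (is.null(dim(vectors))) vectors <- matrix(vectors, nrow = 1)
  if (ncol(vectors) != length(model$weights)) {
    stop("dimension mismatch: vectors have ", ncol(vectors),
         " columns, model expects ", length(model$weights))
  }
  p <- as.numeric(stats::plogis(vectors %*% model$weights + model$bias))
  data.frame(probability = p,
             decision = as.integer(p >= model$threshold))
}

#' Confirm candidate links
#'
#' @param links A `candidate_links` table.
#' @param vectors Matrix of mention vectors aligned row-wise with `links`.
#' @param model A `confirmation_model`.
#' @return The subset of `links` the model confirms, order preserved, with a
#'   `probability` column attached.
#' @export
confirm_links <- function(links, vectors, model) {
  if (nrow(links) == 0) {
    out <- links
    out$probability <- numeric(0)
    return(out)
  }
  pred <- predict_confirmation(model, vectors)
  out <- links
  out$probability <- pred$probability
  out <- out[pred$decision == 1L, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Serialise a confirmation model to JSON
#' @param model A `confirmation_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "confirmation_model"))
  jsonlite::write_json(unclass(model), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a confirmation model from JSON
#' @param path Path written by [save_model()].
#' @return A `confirmation_model`.
#' @export
load_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  model <- list(weights = as.numeric(obj$weights), bias = as.numeric(obj$bias),
                threshold = as.numeric(obj$threshold),
                provenance = obj$provenance, train_meta = obj$train_meta)
  class(model) <- "confirmation_model"
  model
}
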