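#' Four-class macule classifier
#'
#' A small feedforward network maps the 11 macule features to one of
#' four macule types (vascular, petechiae, trophic, trauma). The
#' architecture is fixed: 11 inputs, two hidden layers of 4 neurons
#' with hyperbolic-tangent activations, and a 4-unit logistic-sigmoid
#' output layer trained against one-hot targets in `{0, 1}`.
#'
#' Training minimizes the sum of squared errors by Levenberg-Marquardt:
#' at each iteration the Jacobian `J` of the network outputs with
#' respect to all 88 weights and biases is assembled by
#' backpropagation, and the damped normal equations
#' `(J'J + lambda I) delta = J'e` are solved for the step. A step that
#' reduces the SSE is accepted and `lambda` is divided by 10; otherwise
#' `lambda` is multiplied by 10 and the step retried, so the accepted
#' loss sequence is non-increasing. As `lambda -> 0` the step tends to
#' the Gauss-Newton step, as `lambda -> Inf` to a scaled gradient step.
#' A BFGS fallback (`method = "bfgs"`, via [stats::optim()] with the
#' analytic gradient) is available behind the same interface.
#'
#' `train_network()` performs a stratified split (60% train / 40% test
#' by default), z-scores the features using training-set statistics
#' only ([standardize()]), fits on the training split and reports a
#' confusion matrix, accuracy, and the Pearson correlation R between
#' flattened one-hot targets and network outputs on the held-out split.
#'
#' @param data tibble/data.frame with the 11 [feature_names()] columns
#'   and a `class` column (4 levels, >= 2 examples each).
#' @param train,apply_to feature data frames; statistics come from
#'   `train` only.
#' @param cfg a [train_config()] list.
#' @param object,model a fitted `"macule_net"`.
#' @param newdata data frame with the 11 feature columns (raw scale).
#' @param split train fraction in (0, 1).
#' @param lambda0 initial damping; `max_iter` LM iterations; `tol`
#'   minimum SSE decrease treated as progress.
#' @param val_frac fraction of the training split held out as an
#'   early-stopping validation set (0, the default, trains on the full
#'   split to convergence); `patience` accepted steps without
#'   validation improvement before stopping.
#' @param hidden hidden-layer sizes (fixed at `c(4, 4)` for the macule
#'   classifier).
#' @param seed integer controlling the split and the weight init.
#' @param method `"lm"` (default) or `"bfgs"`.
#' @param x,... method arguments.
#' @return `train_network()` returns a `"macule_net"` object with the
#'   weights, the standardization constants, the class levels, and a
#'   `report` list (confusion matrix, `accuracy`, `regression_r`,
#'   `accuracy_all`, the evaluated counts and the loss trace).
#' @examples
#' feats <- sample_feature_vectors(10, seed = 42)
#' fit <- train_network(feats, train_config(seed = 42))
#' fit$report$accuracy
#' glance(fit)
#' @export
train_network <- function(data, cfg = train_config()) {
  data <- tibble::as_tibble(data)
  stopifnot("class" %in% names(data))
  X <- as.matrix(data[feature_names()])
  if (!all(is.finite(X))) stop("non-finite feature values", call. = FALSE)
  cls <- factor(data$class)
  if (any(table(cls) < 2)) stop("need >= 2 examples per class", call. = FALSE)

  idx <- stratified_split(cls, cfg$split, cfg$seed)
  ztr <- standardize(data[idx$train, ], data[idx$train, ])
  zte <- standardize(data[idx$train, ], data[idx$test, ])
  Xtr <- as.matrix(ztr[feature_names()]); Xte <- as.matrix(zte[feature_names()])
  Ttr <- one_hot(cls[idx$train]); Tte <- one_hot(cls[idx$test])

  # early-stopping validation subset carved out of the training split
  Xv <- NULL; Tv <- NULL
  if (cfg$val_frac > 0 && cfg$method == "lm") {
    vidx <- stratified_split(cls[idx$train], 1 - cfg$val_frac, cfg$seed + 1L)
    Xv <- Xtr[vidx$test, , drop = FALSE]; Tv <- Ttr[vidx$test, , drop = FALSE]
    Xtr <- Xtr[vidx$train, , drop = FALSE]; Ttr <- Ttr[vidx$train, , drop = FALSE]
  }

  params <- withr::with_seed(cfg$seed, init_params(ncol(X), cfg$hidden, nlevels(cls)))
  fit <- if (cfg$method == "bfgs") {
    fit_bfgs(params, Xtr, Ttr, cfg)
  } else {
    fit_lm(params, Xtr, Ttr, cfg, Xv, Tv)
  }

  model <- structure(
    list(params = fit$params, classes = levels(cls),
         center = attr(ztr, "center"), scale = attr(ztr, "scale"),
         cfg = cfg, loss_trace = fit$trace),
    class = "macule_net")

  rep_test <- evaluate_network(model, data[idx$test, ])
  rep_all <- evaluate_network(model, data)
  model$report <- c(rep_test,
                    list(accuracy_all = rep_all$accuracy,
                         n_train = length(idx$train), n_test = length(idx$test)))
  model
}

#' @rdname train_network
#' @export
train_config <- function(split = 0.60, hidden = c(4, 4), lambda0 = 1e-2,
                         max_iter = 150, tol = 1e-10, seed = 1,
                         val_frac = 0, patience = 6,
                         method = c("lm", "bfgs")) {
  stopifnot(split > 0, split < 1, val_frac >= 0, val_frac < 1)
  list(split = split, hidden = hidden, lambda0 = lambda0,
       max_iter = max_iter, tol = tol, seed = as.integer(seed),
       val_frac = val_frac, patience = patience,
       method = match.arg(method))
}

#' @rdname train_network
#' @export
standardize <- function(train, apply_to) {
  train <- tibble::as_tibble(train); apply_to <- tibble::as_tibble(apply_to)
  feats <- intersect(feature_names(), names(train))
  ctr <- vapply(train[feats], mean, double(1))
  scl <- vapply(train[feats], stats::sd, double(1))
  scl[is.na(scl) | scl == 0] <- 1        # constant features pass through centered
  out <- apply_to
  for (f in feats) out[[f]] <- (out[[f]] - ctr[[f]]) / scl[[f]]
  attr(out, "center") <- ctr
  attr(out, "scale") <- scl
  out
}

stratified_split <- function(cls, split, seed) {
  withr::with_seed(seed, {
    train <- integer(0)
    for (lv in levels(cls)) {
      i <- which(cls == lv)
      n_tr <- round(split * length(i))
      n_tr <- max(1L, min(length(i) - 1L, n_tr))
      train <- c(train, sample(i, n_tr))
    }
    list(train = sort(train), test = sort(setdiff(seq_along(cls), train)))
  })
}

one_hot <- function(cls) {
  m <- matrix(0, length(cls), nlevels(cls))
  m[cbind(seq_along(cls), as.integer(cls))] <- 1
  m
}

# ---- network internals ---------------------------------------------------

# small uniform init scaled by fan-in so pre-activations start in the
# linear range of tanh regardless of layer width
init_params <- function(n_in, hidden, n_out) {
  sizes <- c(n_in, hidden, n_out)
  lapply(seq_len(length(sizes) - 1L), function(l) {
    s <- 0.5 / sqrt(sizes[l])
    list(W = matrix(stats::runif(sizes[l + 1] * sizes[l], -s, s),
                    sizes[l + 1], sizes[l]),
         b = stats::runif(sizes[l + 1], -s, s))
  })
}

sigmoid <- function(z) 1 / (1 + exp(-z))

# forward pass, keeping activations; X is n x p
forward_pass <- function(params, X) {
  a <- list(t(X))                              # layers stored as units x n
  L <- length(params)
  for (l in seq_len(L)) {
    z <- params[[l]]$W %*% a[[l]] + params[[l]]$b
    a[[l + 1]] <- if (l < L) tanh(z) else sigmoid(z)
  }
  a
}

#' @rdname train_network
#' @export
predict.macule_net <- function(object, newdata, ...) {
  newdata <- tibble::as_tibble(newdata)
  miss <- setdiff(feature_names(), names(newdata))
  if (length(miss)) stop("missing feature columns: ", paste(miss, collapse = ", "),
                         call. = FALSE)
  X <- as.matrix(newdata[feature_names()])
  X <- sweep(sweep(X, 2, object$center), 2, object$scale, "/")
  out <- t(forward_pass(object$params, X)[[length(object$params) + 1L]])
  colnames(out) <- object$classes
  # ties broken toward the lowest class index (max.col first occurrence)
  pred <- object$classes[apply(out, 1, which.max)]
  tibble::tibble(.pred = factor(pred, levels = object$classes)) |>
    dplyr::bind_cols(tibble::as_tibble(out))
}

pack <- function(params) unlist(lapply(params, function(l) c(l$W, l$b)))

unpack <- function(theta, template) {
  pos <- 0L
  lapply(template, function(l) {
    nw <- length(l$W); nb <- length(l$b)
    W <- matrix(theta[pos + seq_len(nw)], nrow(l$W), ncol(l$W))
    b <- theta[pos + nw + seq_len(nb)]
    pos <<- pos + nw + nb
    list(W = W, b = b)
  })
}

# Jacobian of all outputs w.r.t. all parameters, by backpropagation.
# Rows ordered sample-major: (sample 1 outputs 1..K, sample 2, ...).
network_jacobian <- function(params, X) {
  act <- forward_pass(params, X)
  n <- nrow(X); K <- nrow(params[[length(params)]]$W)
  npar <- length(pack(params))
  J <- matrix(0, n * K, npar)
  L <- length(params)
  offs <- cumsum(c(0, vapply(params, function(l) length(l$W) + length(l$b), double(1))))
  for (i in seq_len(n)) {
    y <- act[[L + 1]][, i]
    S <- diag(y * (1 - y), K)                     # dY/dz at the output layer
    for (l in rev(seq_len(L))) {
      a_prev <- act[[l]][, i]
      cols_W <- offs[l] + seq_len(length(params[[l]]$W))
      cols_b <- offs[l] + length(params[[l]]$W) + seq_len(length(params[[l]]$b))
      rows <- (i - 1L) * K + seq_len(K)
      # dY/dW[l][m, j] = S[k, m] * a_prev[j]; t(a) %x% S lays the columns
      # out in R's column-major storage order of W
      J[rows, cols_W] <- t(a_prev) %x% S
      J[rows, cols_b] <- S
      if (l > 1) S <- (S %*% params[[l]]$W) * rep(1 - act[[l]][, i]^2, each = K)
    }
  }
  J
}

network_sse <- function(params, X, Tm) {
  Y <- t(forward_pass(params, X)[[length(params) + 1L]])
  sum((Tm - Y)^2)
}

fit_lm <- function(params, X, Tm, cfg, Xv = NULL, Tv = NULL) {
  theta <- pack(params)
  template <- params
  lambda <- cfg$lambda0
  sse <- network_sse(params, X, Tm)
  trace <- sse
  watch <- !is.null(Xv) && nrow(Xv) > 0
  best_theta <- theta
  best_val <- if (watch) network_sse(params, Xv, Tv) else Inf
  fails <- 0L
  for (it in seq_len(cfg$max_iter)) {
    cur <- unpack(theta, template)
    J <- network_jacobian(cur, X)
    Y <- t(forward_pass(cur, X)[[length(cur) + 1L]])
    e <- as.vector(t(Tm - Y))                    # sample-major, matches J rows
    g <- crossprod(J, e)
    A <- crossprod(J)
    accepted <- FALSE
    while (lambda <= 1e10) {
      step <- tryCatch(solve(A + lambda * diag(nrow(A)), g),
                       error = function(e) NULL)
      if (!is.null(step)) {
        cand <- theta + as.vector(step)
        cand_sse <- network_sse(unpack(cand, template), X, Tm)
        if (is.finite(cand_sse) && cand_sse < sse) {
          theta <- cand
          improve <- sse - cand_sse
          sse <- cand_sse
          lambda <- max(lambda / 10, 1e-12)
          accepted <- TRUE
          trace <- c(trace, sse)
          if (watch) {
            val <- network_sse(unpack(theta, template), Xv, Tv)
            if (val < best_val) { best_val <- val; best_theta <- theta; fails <- 0L }
            else fails <- fails + 1L
          }
          if (improve < cfg$tol) accepted <- FALSE  # converged on training SSE
          break
        }
      }
      lambda <- lambda * 10
    }
    if (!accepted || (watch && fails >= cfg$patience)) break
  }
  if (!watch) best_theta <- theta
  list(params = unpack(best_theta, template),
       sse = if (watch) network_sse(unpack(best_theta, template), X, Tm) else sse,
       trace = trace)
}

fit_bfgs <- function(params, X, Tm, cfg) {
  template <- params
  fn <- function(theta) network_sse(unpack(theta, template), X, Tm)
  gr <- function(theta) {
    cur <- unpack(theta, template)
    J <- network_jacobian(cur, X)
    Y <- t(forward_pass(cur, X)[[length(cur) + 1L]])
    as.vector(-2 * crossprod(J, as.vector(t(Tm - Y))))
  }
  opt <- stats::optim(pack(params), fn, gr, method = "BFGS",
                      control = list(maxit = 500))
  list(params = unpack(opt$par, template), sse = opt$value, trace = opt$value)
}

#' @rdname train_network
#' @export
evaluate_network <- function(model, data) {
  data <- tibble::as_tibble(data)
  if (nrow(data) == 0) stop("empty evaluation set", call. = FALSE)
  stopifnot(inherits(model, "macule_net"), "class" %in% names(data))
  cls <- factor(data$class, levels = model$classes)
  pr <- predict(model, data)
  conf <- table(truth = cls, predicted = pr$.pred)
  acc <- 100 * mean(as.character(pr$.pred) == as.character(cls))
  targets <- one_hot(cls)
  outputs <- as.matrix(pr[model$classes])
  r <- if (stats::sd(outputs) == 0 || stats::sd(targets) == 0) 0 else
    stats::cor(as.vector(targets), as.vector(outputs))
  list(confusion = conf, accuracy = acc, regression_r = r, n = nrow(data))
}

#' @rdname train_network
#' @export
tidy.macule_net <- function(x, ...) {
  purrr::imap_dfr(x$params, function(l, i) {
    dplyr::bind_rows(
      tibble::tibble(layer = i, term = "weight",
                     unit = as.vector(row(l$W)), input = as.vector(col(l$W)),
                     estimate = as.vector(l$W)),
      tibble::tibble(layer = i, term = "bias",
                     unit = seq_along(l$b), input = NA_integer_,
                     estimate = l$b))
  })
}

#' @rdname train_network
#' @export
glance.macule_net <- function(x, ...) {
  tibble::tibble(
    accuracy = x$report$accuracy,
    regression_r = x$report$regression_r,
    accuracy_all = x$report$accuracy_all,
    n_train = x$report$n_train,
    n_test = x$report$n_test,
    final_sse = x$loss_trace[length(x$loss_trace)],
    iterations = length(x$loss_trace) - 1L)
}

#' Repeat the reference classification experiment over many seeds
#'
#' Draws `n_per_class` feature vectors per macule class from the
#' reference per-class feature distributions
#' ([macule_feature_params()]), trains the network with a stratified
#' 60/40 split, and records held-out accuracy and the target/output
#' regression R — once per seed.
#'
#' @param n_seeds number of replicate seeds.
#' @param n_per_class vectors per class (default 10).
#' @param seed base seed; replicate seeds are derived from it.
#' @param method optimizer passed to [train_config()].
#' @return tibble with one row per replicate: `seed`, `accuracy`,
#'   `regression_r`, `accuracy_all`.
#' @export
run_reference_experiment <- function(n_seeds = 20, n_per_class = 10, seed = 1,
                                     method = "lm") {
  rep_seeds <- withr::with_seed(seed, sample.int(.Machine$integer.max - 1, n_seeds))
  purrr::map_dfr(rep_seeds, function(s) {
    feats <- sample_feature_vectors(n_per_class, seed = s)
    fit <- train_network(feats, train_config(seed = s, method = method))
    tibble::tibble(seed = s,
                   accuracy = fit$report$accuracy,
                   regression_r = fit$report$regression_r,
                   accuracy_all = fit$report$accuracy_all)
  })
}
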