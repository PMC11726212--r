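#' Training configuration
#'
#' @param loss `"bce"` (mean binary cross-entropy against continuous
#'   severity targets, the default) or `"mse"`.
#' @param lr Adam learning rate (default 1e-3).
#' @param batch_size Minibatch size (default 32).
#' @param max_epochs Maximum training epochs (default 100).
#' @param patience Early-stopping patience on validation loss, in epochs
#'   (default 15, must be >= 1).
#' @param seed Integer seed for shuffling.
#' @return An `ad_train_config` list.
#' @export
ad_train_config <- function(loss = c("bce", "mse"), lr = 1e-3,
                            batch_size = 32L, max_epochs = 100L,
                            patience = 15L, seed = 1L) {
  loss <- match.arg(loss)
  if (lr <= 0 || batch_size < 1L || max_epochs < 1L) {
    abort("Learning rate, batch size and max_epochs must be positive.")
  }
  if (patience < 1L) abort("`patience` must be at least 1.")
  structure(list(
    loss = loss, lr = lr, batch_size = as.integer(batch_size),
    max_epochs = as.integer(max_epochs), patience = as.integer(patience),
    seed = as.integer(seed)
  ), class = "ad_train_config")
}

flatten_params <- function(p) unlist(p, use.names = FALSE)

unflatten_params <- function(flat, skeleton) {
  i <- 0L
  rec <- function(sk) {
    if (is.list(sk)) return(lapply(sk, rec))
    n <- length(sk)
    out <- flat[seq.int(i + 1L, length.out = n)]
    i <<- i + n
    if (is.matrix(sk)) dim(out) <- dim(sk)
    out
  }
  rec(skeleton)
}

slice_mats <- function(mats, idx) {
  if (!is.null(mats$X)) return(list(X = mats$X[idx, , drop = FALSE]))
  list(Vg = purrr::map(mats$Vg, ~ .x[idx, , drop = FALSE]),
       direct = mats$direct[idx, , drop = FALSE])
}

model_grad_matrix <- function(model, mats, Y, loss) {
  cfg <- model$config
  if (model$kind == "modular") {
    res <- cpp_modular_grad(
      unname(mats$Vg), mats$direct,
      unname(model$params$embed_W), unname(model$params$embed_B),
      model$params$trunk_W, model$params$trunk_b,
      cfg$activation, cfg$output, cfg$score_scale, Y, loss
    )
    list(loss = res$loss,
         grads = list(embed_W = res$geW, embed_B = res$geB,
                      trunk_W = res$gtW, trunk_b = res$gtb))
  } else {
    res <- cpp_mlp_grad(mats$X, model$params$trunk_W, model$params$trunk_b,
                        cfg$activation, cfg$output, Y, loss)
    list(loss = res$loss, grads = list(trunk_W = res$gtW, trunk_b = res$gtb))
  }
}

eval_loss <- function(model, mats, Y, loss) {
  P <- model_forward_matrix(model, mats)
  Pc <- pmin(1 - 1e-7, pmax(1e-7, P))
  if (loss == "bce") {
    mean(-(Y * log(Pc) + (1 - Y) * log(1 - Pc)))
  } else {
    mean((P - Y)^2)
  }
}

labels_matrix <- function(labels) {
  Y <- as.matrix(labels[, c("lv", "pca", "fv")])
  storage.mode(Y) <- "double"
  Y
}

#' Train a model with Adam and early stopping
#'
#' Minimizes the configured loss (default: mean binary cross-entropy summed
#' over the three severity outputs against continuous targets in \[0, 1\])
#' by minibatch Adam.  Training stops when the validation loss has not
#' improved for `patience` epochs; the parameters from the best validation
#' epoch are kept.  The run is fully reproducible under the configuration
#' seeds.
#'
#' @param model An `ad_model` from [build_model()] or
#'   [build_matched_baseline()].
#' @param train List with `cohort` (normalized) and `labels`, e.g. the
#'   `train` element of [preprocess_cohort()].
#' @param val Same structure, used only for early stopping.
#' @param tc An [ad_train_config()].
#' @return An `ad_fit`: `model` (trained), `history` tibble
#'   (`epoch, train_loss, val_loss`), `best_epoch`, `train_config`.
#' @export
train_model <- function(model, train, val, tc = ad_train_config()) {
  if (nrow(train$cohort) == 0L) abort("Training set is empty.")
  train_mats <- model_matrices(model, train$cohort)
  val_mats <- model_matrices(model, val$cohort)
  Ytr <- labels_matrix(train$labels)
  Yval <- labels_matrix(val$labels)
  check_prob(Ytr, "training labels")
  n <- nrow(Ytr)

  skeleton <- model$params
  theta <- flatten_params(skeleton)
  m_t <- v_t <- numeric(length(theta))
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  step <- 0L

  best_val <- Inf
  best_theta <- theta
  best_epoch <- 0L
  wait <- 0L
  history <- vector("list", tc$max_epochs)

  withr::with_seed(tc$seed, {
    for (epoch in seq_len(tc$max_epochs)) {
      idx <- sample.int(n)
      for (start in seq(1L, n, by = tc$batch_size)) {
        batch <- idx[seq.int(start, min(start + tc$batch_size - 1L, n))]
        g <- model_grad_matrix(model, slice_mats(train_mats, batch),
                               Ytr[batch, , drop = FALSE], tc$loss)
        if (!is.finite(g$loss)) {
          abort(sprintf(
            "Non-finite loss (%g) at epoch %d; inspect learning rate and inputs.",
            g$loss, epoch))
        }
        grad <- flatten_params(g$grads)
        step <- step + 1L
        m_t <- b1 * m_t + (1 - b1) * grad
        v_t <- b2 * v_t + (1 - b2) * grad^2
        mhat <- m_t / (1 - b1^step)
        vhat <- v_t / (1 - b2^step)
        theta <- theta - tc$lr * mhat / (sqrt(vhat) + eps)
        model$params <- unflatten_params(theta, skeleton)
      }
      tr_loss <- eval_loss(model, train_mats, Ytr, tc$loss)
      val_loss <- eval_loss(model, val_mats, Yval, tc$loss)
      history[[epoch]] <- tibble::tibble(
        epoch = epoch, train_loss = tr_loss, val_loss = val_loss)
      if (val_loss < best_val) {
        best_val <- val_loss
        best_theta <- theta
        best_epoch <- epoch
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= tc$patience) break
      }
    }
  })
  model$params <- unflatten_params(best_theta, skeleton)
  structure(list(
    model = model,
    history = dplyr::bind_rows(history),
    best_epoch = best_epoch,
    best_val_loss = best_val,
    train_config = tc
  ), class = "ad_fit")
}

#' @export
predict.ad_fit <- function(object, newdata, ...) {
  forward(object$model, newdata)
}

#' @export
print.ad_fit <- function(x, ...) {
  cat(sprintf(
    "<ad_fit> %s | %d epochs run, best epoch %d (val loss %.5f)\n",
    if (x$model$kind == "modular") "grouped-attention model" else "baseline MLP",
    nrow(x$history), x$best_epoch, x$best_val_loss
  ))
  invisible(x)
}

#' Tidy the training history of a fitted model
#'
#' @param x An `ad_fit`.
#' @param ... Unused.
#' @return Long tibble with `epoch`, `dataset` (train/val), `loss`.
#' @export
tidy.ad_fit <- function(x, ...) {
  tidyr::pivot_longer(x$history, -"epoch", names_to = "dataset",
                      values_to = "loss") |>
    dplyr::mutate(dataset = sub("_loss$", "", .data$dataset))
}

#' One-row summary of a fitted model
#'
#' @param x An `ad_fit`.
#' @param ... Unused.
#' @return Tibble with model kind, parameter count, epochs run, best epoch
#'   and best validation loss.
#' @export
glance.ad_fit <- function(x, ...) {
  tibble::tibble(
    kind = x$model$kind,
    n_parameters = count_parameters(x$model),
    epochs_run = nrow(x$history),
    best_epoch = x$best_epoch,
    best_val_loss = x$best_val_loss,
    loss = x$train_config$loss
  )
}

#' Plot training and validation loss curves
#'
#' @param object An `ad_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ad_fit <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$epoch, y = .data$loss,
                               colour = .data$dataset)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$best_epoch, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::labs(x = "Epoch", y = "Loss", colour = NULL,
                  title = "Training history",
                  subtitle = sprintf("best validation epoch: %d", object$best_epoch)) +
    ggplot2::theme_minimal()
}

#' Plot attention weights as a heatmap
#'
#' Averages the row-stochastic attention matrices over patients, per group.
#'
#' @param model A modular `ad_model` (or `ad_fit`).
#' @param cohort Normalized cohort tibble.
#' @param group Group to plot (default `"G2_biochem"`).
#' @return A ggplot.
#' @export
plot_attention <- function(model, cohort, group = "G2_biochem") {
  if (inherits(model, "ad_fit")) model <- model$model
  aw <- attention_weights(model, cohort, group) |>
    dplyr::summarise(weight = mean(.data$weight), .by = c("from", "to"))
  ggplot2::ggplot(aw, ggplot2::aes(x = .data$to, y = .data$from,
                                   fill = .data$weight)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(title = paste("Mean attention weights:", group),
                  x = "attended feature", y = "query feature") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
  }
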