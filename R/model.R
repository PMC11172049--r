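#' Wavelet CNN architecture configuration
#'
#' The network is a VGG-style stack: 3x3 convolutions with 1x1 padding,
#' spatial downsampling by stride-2 3x3 convolutions (no pooling), batch
#' normalisation before every ReLU, and a global-average-pooling readout
#' feeding a linear class head.  At every dyadic scale the four Haar
#' sub-band planes of the input (per channel) are concatenated channel-wise
#' into the feature maps of matching spatial size, and a 1x1 projection
#' shortcut restores the running channel width after each concatenation.
#'
#' `block_widths` holds one output width per stage (stages `0..levels`).
#' The default widths for the reference 224-pixel, 4-level, 5-grade
#' configuration are `c(72, 144, 312, 696, 517)`: near-doubling widths
#' calibrated once so that the total number of trainable scalars is exactly
#' 11,799,109, and then frozen.
#'
#' @param input_side Input image side in pixels; must be divisible by
#'   `2^levels`.
#' @param input_channels Number of image channels (3 for RGB).
#' @param levels Haar decomposition depth `T`; one sub-band injection per
#'   level.
#' @param block_widths Integer vector of `levels + 1` conv output widths.
#'   `NULL` picks the frozen reference table when `levels == 4` and a
#'   doubling ladder `24 * 2^stage` otherwise.
#' @param num_classes Number of output grades.
#' @param seed Seed for weight initialisation.
#' @return A `wcnn_config` list.
#' @export
wcnn_config <- function(input_side = 224L, input_channels = 3L, levels = 4L,
                        block_widths = NULL, num_classes = 5L, seed = 1L) {
  input_side <- as.integer(input_side); levels <- as.integer(levels)
  if (input_side %% 2L^levels != 0L)
    stop(sprintf("input_side (%d) must be divisible by 2^levels (%d)",
                 input_side, 2L^levels), call. = FALSE)
  if (is.null(block_widths)) {
    block_widths <- if (levels == 4L) c(72L, 144L, 312L, 696L, 517L)
                    else as.integer(24L * 2L^(0:levels))
  }
  block_widths <- as.integer(block_widths)
  if (length(block_widths) != levels + 1L)
    stop(sprintf("block_widths must have levels + 1 = %d entries, got %d",
                 levels + 1L, length(block_widths)), call. = FALSE)
  structure(list(input_side = input_side,
                 input_channels = as.integer(input_channels),
                 levels = levels, block_widths = block_widths,
                 num_classes = as.integer(num_classes),
                 seed = as.integer(seed)),
            class = "wcnn_config")
}

#' Desk-scale configuration for quick experiments
#'
#' A small 64-pixel, 2-level variant of the architecture (~10^5
#' parameters) used by the end-to-end examples and tests.
#'
#' @inheritParams wcnn_config
#' @return A `wcnn_config`.
#' @export
wcnn_tiny_config <- function(input_side = 64L, levels = 2L,
                             block_widths = c(24L, 48L, 96L),
                             num_classes = 5L, seed = 1L) {
  wcnn_config(input_side = input_side, input_channels = 3L, levels = levels,
              block_widths = block_widths, num_classes = num_classes, seed = seed)
}

# Layer descriptor plan for a config; pure bookkeeping, no weights.
wcnn_plan <- function(config) {
  S <- config$input_side; C <- config$input_channels
  T <- config$levels; w <- config$block_widths
  inj_ch <- 4L * C
  layers <- list()
  add <- function(l) layers[[length(layers) + 1L]] <<- l
  conv <- function(name, k, stride, in_ch, out_ch, side_in) {
    list(kind = "conv", name = name, k = k, stride = stride,
         pad = if (k == 3L) 1L else 0L, in_ch = in_ch, out_ch = out_ch,
         side_in = side_in, side_out = side_in %/% stride, bn = TRUE, act = TRUE)
  }
  add(conv("conv0a", 3L, 1L, C, w[1], S))
  add(conv("conv0b", 3L, 2L, w[1], w[1], S))
  side <- S %/% 2L
  cur <- w[1]
  for (t in seq_len(T)) {
    add(list(kind = "inject", name = sprintf("inject%d", t), level = t,
             in_ch = cur, out_ch = cur + inj_ch, side_in = side, side_out = side))
    add(conv(sprintf("proj%d", t), 1L, 1L, cur + inj_ch, cur, side))
    add(conv(sprintf("conv%da", t), 3L, 1L, cur, w[t + 1L], side))
    cur <- w[t + 1L]
    if (t < T) {
      add(conv(sprintf("conv%db", t), 3L, 2L, cur, cur, side))
      side <- side %/% 2L
    }
  }
  add(list(kind = "gap", name = "gap", in_ch = cur, out_ch = cur,
           side_in = side, side_out = 1L))
  add(list(kind = "dense", name = "head", in_ch = cur, out_ch = config$num_classes,
           side_in = 1L, side_out = 1L))
  layers
}

#' Build a Wavelet CNN
#'
#' Instantiates the network for a configuration: lays out the layer table,
#' checks that the sub-band spatial size matches the feature-map size at
#' every injection point, and initialises all weights (He-normal, seeded).
#'
#' @param config A [wcnn_config()].
#' @return An object of class `wcnn_network` holding the layer table,
#'   parameter arrays, and batch-norm running statistics.
#' @examples
#' net <- build_network(wcnn_tiny_config())
#' count_parameters(net)
#' @export
build_network <- function(config) {
  stopifnot(inherits(config, "wcnn_config"))
  layers <- wcnn_plan(config)
  # audit injection scales before allocating anything
  for (l in layers) {
    if (l$kind == "inject") {
      want <- config$input_side %/% 2L^l$level
      if (l$side_in != want)
        stop(sprintf("layer %s: feature-map side %d but level-%d sub-bands have side %d",
                     l$name, l$side_in, l$level, want), call. = FALSE)
    }
  }
  params <- list(); buffers <- list()
  rng <- local_rng(config$seed)
  on.exit(rng(), add = TRUE)
  for (l in layers) {
    if (l$kind == "conv") {
      fan_in <- l$k * l$k * l$in_ch
      params[[paste0(l$name, ".W")]] <-
        array(stats::rnorm(l$k * l$k * l$in_ch * l$out_ch, sd = sqrt(2 / fan_in)),
              c(l$k, l$k, l$in_ch, l$out_ch))
      params[[paste0(l$name, ".b")]] <- numeric(l$out_ch)
      params[[paste0(l$name, ".gamma")]] <- rep(1, l$out_ch)
      params[[paste0(l$name, ".beta")]] <- numeric(l$out_ch)
      buffers[[paste0(l$name, ".rmean")]] <- numeric(l$out_ch)
      buffers[[paste0(l$name, ".rvar")]] <- rep(1, l$out_ch)
    } else if (l$kind == "dense") {
      params[[paste0(l$name, ".W")]] <-
        matrix(stats::rnorm(l$in_ch * l$out_ch, sd = sqrt(2 / l$in_ch)),
               l$in_ch, l$out_ch)
      params[[paste0(l$name, ".b")]] <- numeric(l$out_ch)
    }
  }
  structure(list(config = config, layers = layers, params = params,
                 buffers = buffers, trained = FALSE, history = NULL),
            class = "wcnn_network")
}

# run fn under a private RNG stream; returns the restore function
local_rng <- function(seed) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  function() {
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }
}

#' Number of trainable parameters
#'
#' Sums every trainable scalar in the network: convolution and dense
#' weights and biases, and batch-norm scale/shift.  The fixed Haar analysis
#' filters and the batch-norm running statistics are not trainable and are
#' never counted.
#'
#' @param network A `wcnn_network`.
#' @return A single non-negative number.
#' @export
count_parameters <- function(network) {
  stopifnot(inherits(network, "wcnn_network"))
  sum(vapply(network$params, length, integer(1)))
}

#' Layer table of a network
#'
#' One row per layer with kernel size, stride, padding, channel counts,
#' spatial sides, per-layer trainable parameter count, and whether the
#' layer is a sub-band injection point.
#'
#' @param network A `wcnn_network`.
#' @return A data.frame.
#' @export
wcnn_layer_table <- function(network) {
  stopifnot(inherits(network, "wcnn_network"))
  rows <- lapply(network$layers, function(l) {
    np <- sum(vapply(grep(paste0("^", l$name, "\\."), names(network$params), value = TRUE),
                     function(nm) length(network$params[[nm]]), integer(1)))
    data.frame(name = l$name, kind = l$kind,
               kernel = if (l$kind %in% c("conv")) l$k else NA_integer_,
               stride = if (l$kind == "conv") l$stride else NA_integer_,
               padding = if (l$kind == "conv") l$pad else NA_integer_,
               in_ch = l$in_ch, out_ch = l$out_ch,
               side_in = l$side_in, side_out = l$side_out,
               injection = l$kind == "inject",
               n_params = np, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# Per-level injection matrices for a batch: list over t of (h*w*N) x 4C
# matrices with column order (ll_1..C, lh_1..C, hl_1..C, hh_1..C).
wcnn_injections <- function(x, T, filters = haar_filter_pair()) {
  d <- dim(x)
  out <- vector("list", T)
  for (t in seq_len(T)) {
    h <- d[1] %/% 2L^t
    arr <- array(0, c(h, h, 4L * d[3], d[4]))
    out[[t]] <- arr
  }
  for (n in seq_len(d[4])) {
    stk <- wavelet_decompose(x[, , , n, drop = TRUE], T, filters)
    for (t in seq_len(T)) {
      s <- stk$levels[[t]]
      ch <- d[3]
      out[[t]][, , 1:ch, n] <- s$ll
      out[[t]][, , (ch + 1L):(2L * ch), n] <- s$lh
      out[[t]][, , (2L * ch + 1L):(3L * ch), n] <- s$hl
      out[[t]][, , (3L * ch + 1L):(4L * ch), n] <- s$hh
    }
  }
  lapply(out, to_mat)
}

# Forward pass.  x: H x W x C x N.  Returns logits, GAP features and, when
# training, the caches needed for backprop plus updated BN buffers.
# Internally activations travel in the flat matrix layout of layers.R.
wcnn_forward <- function(network, x, training = FALSE, keep_cache = FALSE) {
  cfg <- network$config
  d <- dim(x)
  if (length(d) != 4L || d[1] != cfg$input_side || d[2] != cfg$input_side ||
      d[3] != cfg$input_channels)
    stop(sprintf("input must be %d x %d x %d x N, got %s",
                 cfg$input_side, cfg$input_side, cfg$input_channels,
                 paste(d, collapse = " x ")), call. = FALSE)
  inj <- wcnn_injections(x, cfg$levels)
  p <- network$params; buf <- network$buffers
  caches <- list()
  feats <- NULL
  cur <- to_mat(x)
  hwn <- c(d[1], d[2], d[4])
  for (li in seq_along(network$layers)) {
    l <- network$layers[[li]]
    if (l$kind == "conv") {
      cv <- conv_forward(cur, hwn, p[[paste0(l$name, ".W")]], p[[paste0(l$name, ".b")]],
                         l$stride, l$pad, keep_cache = keep_cache)
      bn <- bn_forward(cv$out, p[[paste0(l$name, ".gamma")]], p[[paste0(l$name, ".beta")]],
                       training, buf[[paste0(l$name, ".rmean")]], buf[[paste0(l$name, ".rvar")]],
                       keep_cache = keep_cache)
      if (training) {
        buf[[paste0(l$name, ".rmean")]] <- bn$rmean
        buf[[paste0(l$name, ".rvar")]] <- bn$rvar
      }
      rl <- relu_forward(bn$out)
      cur <- rl$out
      hwn <- cv$hwn
      if (keep_cache) caches[[li]] <- list(conv = cv$cache, bn = bn$cache, mask = rl$mask)
    } else if (l$kind == "inject") {
      cur <- cbind(cur, inj[[l$level]])
      if (keep_cache) caches[[li]] <- list(orig_ch = l$in_ch)
    } else if (l$kind == "gap") {
      feats <- gap_forward(cur, hwn)      # N x C
      cur <- feats
      if (keep_cache) caches[[li]] <- list(hwn = hwn)
    } else if (l$kind == "dense") {
      logits <- cur %*% p[[paste0(l$name, ".W")]]
      logits <- logits + rep(p[[paste0(l$name, ".b")]], each = nrow(logits))
      if (keep_cache) caches[[li]] <- list(input = cur)
      cur <- logits
    }
  }
  list(logits = cur, features = feats, caches = caches, buffers = buf)
}

# Backward pass from dlogits; returns named gradient list matching params.
wcnn_backward <- function(network, caches, dlogits) {
  p <- network$params
  grads <- list()
  dcur <- dlogits
  for (li in rev(seq_along(network$layers))) {
    l <- network$layers[[li]]
    if (l$kind == "dense") {
      inp <- caches[[li]]$input
      grads[[paste0(l$name, ".W")]] <- crossprod(inp, dcur)
      grads[[paste0(l$name, ".b")]] <- colSums(dcur)
      dcur <- tcrossprod(dcur, p[[paste0(l$name, ".W")]])
    } else if (l$kind == "gap") {
      dcur <- gap_backward(dcur, caches[[li]]$hwn)
    } else if (l$kind == "inject") {
      dcur <- dcur[, seq_len(caches[[li]]$orig_ch), drop = FALSE]
    } else if (l$kind == "conv") {
      dcur <- dcur * caches[[li]]$mask
      bb <- bn_backward(dcur, caches[[li]]$bn)
      grads[[paste0(l$name, ".gamma")]] <- bb$dgamma
      grads[[paste0(l$name, ".beta")]] <- bb$dbeta
      cb <- conv_backward(bb$dx, caches[[li]]$conv)
      grads[[paste0(l$name, ".W")]] <- cb$dw
      grads[[paste0(l$name, ".b")]] <- cb$db
      dcur <- cb$dx
    }
  }
  grads
}

#' Training configuration
#'
#' @param learning_rate Adam step size.
#' @param batch_size Mini-batch size.
#' @param max_epochs Upper bound on epochs.
#' @param patience Early-stopping patience: training halts when the
#'   monitored training accuracy has not improved for this many epochs,
#'   and the best-scoring weights are restored.
#' @param seed Seed controlling shuffling (weight init is seeded by the
#'   model config).
#' @return A `wcnn_train_config` list.
#' @export
wcnn_train_config <- function(learning_rate = 1e-3, batch_size = 16L,
                              max_epochs = 50L, patience = 5L, seed = 1L) {
  stopifnot(max_epochs >= 1L)
  structure(list(learning_rate = learning_rate, batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs), patience = as.integer(patience),
                 seed = as.integer(seed)),
            class = "wcnn_train_config")
}

#' Train a Wavelet CNN
#'
#' Minimises softmax cross-entropy with Adam over shuffled mini-batches.
#' Training accuracy and loss are recorded per epoch (accumulated from the
#' training-mode forward passes), and early stopping restores the weights
#' of the best epoch.  Fully reproducible for fixed seeds: shuffling is the
#' only source of randomness and is driven by `cfg$seed`.
#'
#' @param network A `wcnn_network` from [build_network()].
#' @param x `H x W x C x N` array of preprocessed images.
#' @param y Integer grades in `0..(num_classes-1)`.
#' @param cfg A [wcnn_train_config()].
#' @return The trained network, with `$history` a data.frame of per-epoch
#'   `loss` and `accuracy` and `$trained = TRUE`.
#' @export
wcnn_train <- function(network, x, y, cfg = wcnn_train_config()) {
  stopifnot(inherits(network, "wcnn_network"))
  n <- dim(x)[4]
  if (n == 0L) stop("empty training set", call. = FALSE)
  K <- network$config$num_classes
  y <- as.integer(y)
  if (length(y) != n) stop("length(y) must equal the batch dimension of x", call. = FALSE)
  if (any(y < 0L | y >= K))
    stop(sprintf("labels must lie in 0..%d", K - 1L), call. = FALSE)
  y1 <- y + 1L
  restore <- local_rng(cfg$seed)
  on.exit(restore(), add = TRUE)
  opt <- adam_init(network$params)
  best_acc <- -Inf; best <- NULL; since_best <- 0L
  hist <- data.frame(epoch = integer(0), loss = numeric(0), accuracy = numeric(0))
  for (epoch in seq_len(cfg$max_epochs)) {
    idx <- sample.int(n)
    tot_loss <- 0; tot_correct <- 0L
    for (start in seq.int(1L, n, cfg$batch_size)) {
      bi <- idx[start:min(start + cfg$batch_size - 1L, n)]
      xb <- x[, , , bi, drop = FALSE]
      fw <- wcnn_forward(network, xb, training = TRUE, keep_cache = TRUE)
      network$buffers <- fw$buffers
      sx <- softmax_xent(fw$logits, y1[bi])
      tot_loss <- tot_loss + sx$loss * length(bi)
      tot_correct <- tot_correct + sum(max.col(sx$probs, ties.method = "first") == y1[bi])
      grads <- wcnn_backward(network, fw$caches, sx$dlogits)
      st <- adam_step(network$params, grads, opt, cfg$learning_rate)
      network$params <- st$params; opt <- st$state
    }
    acc <- tot_correct / n
    hist <- rbind(hist, data.frame(epoch = epoch, loss = tot_loss / n, accuracy = acc))
    if (acc > best_acc + 1e-12) {
      best_acc <- acc
      best <- list(params = network$params, buffers = network$buffers)
      since_best <- 0L
    } else {
      since_best <- since_best + 1L
      if (since_best >= cfg$patience) break
    }
  }
  if (!is.null(best)) {
    network$params <- best$params
    network$buffers <- best$buffers
  }
  network$history <- hist
  network$trained <- TRUE
  network
}

#' Extract global-average-pooling features
#'
#' Runs a deterministic (evaluation-mode) forward pass and returns the
#' spatial mean of the final convolutional feature map for each image:
#' one row per image, one column per channel entering the pooling layer.
#'
#' @param network A `wcnn_network` (trained or not).
#' @param x `H x W x C x N` array.
#' @return An `N x d` numeric matrix.
#' @export
extract_features <- function(network, x) {
  fw <- wcnn_forward(network, x, training = FALSE, keep_cache = FALSE)
  fw$features
}

# class probabilities from the network's own softmax head
wcnn_predict_probs <- function(network, x) {
  fw <- wcnn_forward(network, x, training = FALSE)
  softmax_rows(fw$logits)
}

#' Save / load a network checkpoint
#'
#' @param network A `wcnn_network`.
#' @param path File path for the single-archive checkpoint.
#' @return `wcnn_save` returns `path` invisibly; `wcnn_load` returns the
#'   network.
#' @export
wcnn_save <- function(network, path) {
  saveRDS(network, path)
  invisible(path)
}

#' @rdname wcnn_save
#' @export
wcnn_load <- function(path) {
  net <- readRDS(path)
  stopifnot(inherits(net, "wcnn_network"))
  net
}

#' Export the layer table as JSON
#'
#' @param network A `wcnn_network`.
#' @param path Optional file to write to.
#' @return The JSON string, invisibly if written to file.
#' @export
wcnn_layer_table_json <- function(network, path = NULL) {
  js <- jsonlite::toJSON(wcnn_layer_table(network), dataframe = "rows", pretty = TRUE)
  if (!is.null(path)) { writeLines(js, path); return(invisible(js)) }
  js
}

#' @export
print.wcnn_network <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("Wavelet CNN: %d x %d x %d input, %d Haar levels, %d classes\n",
              cfg$input_side, cfg$input_side, cfg$input_channels,
              cfg$levels, cfg$num_classes))
  cat(sprintf("  stage widths: %s\n", paste(cfg$block_widths, collapse = ", ")))
  cat(sprintf("  trainable parameters: %s\n",
              format(count_parameters(x), big.mark = ",")))
  cat(sprintf("  trained: %s\n", x$trained))
  invisible(x)
}
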