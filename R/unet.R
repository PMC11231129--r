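#' Residual 3D U-Net specification
#'
#' A fully convolutional encoder–decoder over 3D patches with skip
#' connections at each resolution level, wrapped in a logit/sigmoid
#' bypass: the network body predicts a correction that is added to the
#' inverse-sigmoid of the (clamped) input before a final sigmoid, so a
#' zero body output reproduces the input exactly and outputs are always
#' in (0, 1). The bypass also anchors intensities near 0 and 1, where the
#' logit is steep, making it hard for the network to move extreme values.
#'
#' @param depth number of resolution levels (>= 1; each extra level
#'   halves the grid, so the input dims must be divisible by
#'   `2^(depth-1)`).
#' @param base_channels feature channels at full resolution.
#' @param channel_growth multiplier per level.
#' @param bypass_epsilon clamp margin for the logit transform, in
#'   (0, 0.5); the logit is undefined at exactly 0 and 1.
#' @return An object of class `unet_spec`.
#' @export
unet_spec <- function(depth = 3L, base_channels = 16L, channel_growth = 2,
                      bypass_epsilon = 1e-4) {
  depth <- as.integer(depth)
  base_channels <- as.integer(base_channels)
  stopifnot(depth >= 1L, base_channels >= 1L, channel_growth >= 1,
            bypass_epsilon > 0, bypass_epsilon < 0.5)
  structure(list(depth = depth, base_channels = base_channels,
                 channel_growth = channel_growth,
                 bypass_epsilon = bypass_epsilon),
            class = "unet_spec")
}

level_channels <- function(spec)
  as.integer(round(spec$base_channels * spec$channel_growth^(seq_len(spec$depth) - 1)))

#' Build (initialise) a residual U-Net model
#'
#' Convolution weights use He initialisation. The final (head)
#' convolution gets small random weights by default, so the untrained
#' network starts close to — but not exactly at — the bypass identity:
#' an exactly zero head blocks all gradient flow into the body at the
#' first optimisation step (the body gradient is the head-weight matrix
#' times the output gradient), which can leave the network permanently
#' stuck for unlucky initialisations. `head_init = "zero"` builds the
#' exact-identity network (useful for verifying the bypass contract).
#'
#' @param spec a [unet_spec()].
#' @param seed integer seed for the weight draw.
#' @param head_init `"small"` (default; sd 0.01) or `"zero"`.
#' @return An object of class `unet_model` (list of `spec` and `params`).
#' @export
build_model <- function(spec = unet_spec(), seed = 1L,
                        head_init = c("small", "zero")) {
  head_init <- match.arg(head_init)
  stopifnot(inherits(spec, "unet_spec"))
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  ch <- level_channels(spec)
  p <- list()
  mk <- function(cin, cout, sd = sqrt(2 / (27 * cin))) {
    w <- if (sd == 0) matrix(0, 27 * cin, cout) else
      matrix(stats::rnorm(27 * cin * cout, 0, sd), 27 * cin, cout)
    list(W = w, b = numeric(cout))
  }
  for (l in seq_len(spec$depth)) {
    cin <- if (l == 1L) 1L else ch[l - 1L]
    p[[sprintf("enc%d_a", l)]] <- mk(cin, ch[l])
    p[[sprintf("enc%d_b", l)]] <- mk(ch[l], ch[l])
  }
  if (spec$depth > 1L) for (l in seq_len(spec$depth - 1L)) {
    p[[sprintf("dec%d_u", l)]] <- mk(ch[l + 1L], ch[l])
    p[[sprintf("dec%d_b", l)]] <- mk(ch[l], ch[l])
  }
  p[["head"]] <- mk(ch[1L], 1L,
                    sd = if (head_init == "zero") 0 else 0.01)
  structure(list(spec = spec, params = p), class = "unet_model")
}

#' @export
print.unet_model <- function(x, ...) {
  n <- sum(vapply(x$params, function(q) length(q$W) + length(q$b), numeric(1)))
  cat(sprintf("<unet_model> depth %d, channels %s, %d parameters\n",
              x$spec$depth, paste(level_channels(x$spec), collapse = "/"),
              as.integer(n)))
  invisible(x)
}

conv_fwd <- function(x, layer) {
  conv3d_fwd_cpp(x, dim(x), layer$W, layer$b)
}

# leaky rectifier: a small negative-side slope keeps gradients alive in
# units whose pre-activations go all-negative (plain ReLU can collapse a
# small network into a dead, untrainable state)
lrelu_alpha <- 0.1

lrelu <- function(a) {
  h <- pmax(a, 0) + lrelu_alpha * pmin(a, 0)
  dim(h) <- dim(a)
  h
}

avgpool2 <- function(x) {
  d <- dim(x)
  if (any(d[1:3] %% 2L != 0L))
    stop("U-Net too deep for this input: odd grid at a pooling stage",
         call. = FALSE)
  x1 <- x[seq(1, d[1], 2), , , , drop = FALSE] +
        x[seq(2, d[1], 2), , , , drop = FALSE]
  x2 <- x1[, seq(1, d[2], 2), , , drop = FALSE] +
        x1[, seq(2, d[2], 2), , , drop = FALSE]
  x3 <- x2[, , seq(1, d[3], 2), , drop = FALSE] +
        x2[, , seq(2, d[3], 2), , drop = FALSE]
  x3 / 8
}

upsample2 <- function(x) {
  d <- dim(x)
  x <- x[rep(seq_len(d[1]), each = 2), , , , drop = FALSE]
  x <- x[, rep(seq_len(d[2]), each = 2), , , drop = FALSE]
  x[, , rep(seq_len(d[3]), each = 2), , drop = FALSE]
}

# forward pass; cache holds everything backward needs
unet_forward <- function(model, x, keep_cache = FALSE) {
  spec <- model$spec; p <- model$params
  L <- spec$depth
  eps <- spec$bypass_epsilon
  d <- dim(x)
  stopifnot(length(d) == 3L)
  if (L > 1L && any(d %% (2L^(L - 1L)) != 0L))
    stop(sprintf("input dims (%s) must be divisible by %d for depth %d",
                 paste(d, collapse = ","), 2L^(L - 1L), L), call. = FALSE)
  x4 <- x; dim(x4) <- c(d, 1L)
  cache <- list(x = x)
  enc <- vector("list", L)
  cur <- x4
  for (l in seq_len(L)) {
    if (l > 1L) {
      cache[[sprintf("pool%d_in_dim", l)]] <- dim(cur)
      cur <- avgpool2(cur)
    }
    cache[[sprintf("enc%d_a_in", l)]] <- cur
    a1 <- conv_fwd(cur, p[[sprintf("enc%d_a", l)]])
    h1 <- lrelu(a1)
    cache[[sprintf("enc%d_a_pre", l)]] <- a1
    cache[[sprintf("enc%d_b_in", l)]] <- h1
    a2 <- conv_fwd(h1, p[[sprintf("enc%d_b", l)]])
    h2 <- lrelu(a2)
    cache[[sprintf("enc%d_b_pre", l)]] <- a2
    enc[[l]] <- h2
    cur <- h2
  }
  if (L > 1L) for (l in rev(seq_len(L - 1L))) {
    # channel-reducing conv at the coarse level, then upsample: cheaper
    # than convolving the upsampled grid, same receptive-field family
    cache[[sprintf("dec%d_u_in", l)]] <- cur
    a3 <- conv_fwd(cur, p[[sprintf("dec%d_u", l)]])
    h3 <- lrelu(a3)
    cache[[sprintf("dec%d_u_pre", l)]] <- a3
    s <- upsample2(h3) + enc[[l]]
    cache[[sprintf("dec%d_b_in", l)]] <- s
    a4 <- conv_fwd(s, p[[sprintf("dec%d_b", l)]])
    h4 <- lrelu(a4)
    cache[[sprintf("dec%d_b_pre", l)]] <- a4
    cur <- h4
  }
  cache[["head_in"]] <- cur
  r <- conv_fwd(cur, p[["head"]])
  dim(r) <- d
  xc <- pmin(pmax(x, eps), 1 - eps)
  z <- log(xc / (1 - xc)) + r
  out <- 1 / (1 + exp(-z))
  cache[["out"]] <- out
  if (keep_cache) list(out = out, cache = cache) else list(out = out)
}

# backward pass: returns parameter gradients given dL/dout
unet_backward <- function(model, cache, dout) {
  spec <- model$spec; p <- model$params
  L <- spec$depth
  out <- cache$out
  dz <- dout * out * (1 - out)
  grads <- list()
  conv_bwd <- function(name, dy, need_dx = TRUE) {
    xin <- cache[[paste0(name, "_in")]]
    res <- conv3d_bwd_cpp(xin, dim(xin), p[[name]]$W, dy, need_dx)
    grads[[name]] <<- list(W = res$dW, b = res$db)
    if (need_dx) res$dx else NULL
  }
  drelu <- function(name, dh) {
    pre <- cache[[paste0(name, "_pre")]]
    dh * ((pre > 0) + lrelu_alpha * (pre <= 0))
  }
  d <- dim(cache$x)
  dr <- dz; dim(dr) <- c(d, 1L)
  dcur <- conv_bwd("head", dr, need_dx = TRUE)
  denc <- vector("list", L)   # gradient w.r.t. enc[[l]] outputs via skips
  if (L > 1L) for (l in seq_len(L - 1L)) {
    da4 <- drelu(sprintf("dec%d_b", l), dcur)
    ds <- conv_bwd(sprintf("dec%d_b", l), da4, need_dx = TRUE)
    denc[[l]] <- ds                      # skip branch
    dh3 <- avgpool2(ds) * 8             # backward of nearest upsample
    da3 <- drelu(sprintf("dec%d_u", l), dh3)
    dcur <- conv_bwd(sprintf("dec%d_u", l), da3, need_dx = TRUE)
  }
  # dcur now sits at enc[[L]]'s output
  dh2 <- dcur
  for (l in rev(seq_len(L))) {
    if (l < L && !is.null(denc[[l]])) dh2 <- dh2 + denc[[l]]
    da2 <- drelu(sprintf("enc%d_b", l), dh2)
    dh1 <- conv_bwd(sprintf("enc%d_b", l), da2, need_dx = TRUE)
    da1 <- drelu(sprintf("enc%d_a", l), dh1)
    need <- l > 1L
    dprev <- conv_bwd(sprintf("enc%d_a", l), da1, need_dx = need)
    if (need) {
      # backward of average pooling: spread dy/8 to the 2x2x2 children
      dh2 <- upsample2(dprev / 8)
    }
  }
  grads
}

#' Apply the network to a single normalized patch or conforming volume
#'
#' @param model a [build_model()] result.
#' @param x 3D array with values in [0, 1]; dims must be divisible by
#'   `2^(depth-1)`.
#' @return 3D array of the same shape, values in (0, 1).
#' @export
unet_predict <- function(model, x) {
  stopifnot(inherits(model, "unet_model"))
  unet_forward(model, x)$out
}
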