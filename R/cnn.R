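# Compact seeded convolutional-network engine.
#
# The classifier is a scaled-down VGG-style network: n_blocks stacked
# (conv3x3 - ReLU - conv3x3 - ReLU - maxpool2) blocks followed by a dense
# ReLU layer and a softmax head.  Convolutions are evaluated as im2col
# gathers followed by BLAS matrix products, so everything runs in base R
# at speeds adequate for desk-scale images.  Multi-input networks hold one
# convolutional trunk per image modality; the flattened trunk features are
# concatenated before the dense head.

# ---------------------------------------------------------------------------
# geometry caches -----------------------------------------------------------

.hs_geom <- new.env(parent = emptyenv())

conv_geom <- function(C, H, W) {
  key <- paste("c", C, H, W, sep = "_")
  g <- .hs_geom[[key]]
  if (!is.null(g)) return(g)
  Hp <- H + 2L; Wp <- W + 2L
  HpWp <- Hp * Wp
  # interior (unpadded) positions within one channel, y fastest
  int1 <- as.vector(outer(seq_len(H), seq_len(W), function(y, x) x * Hp + y + 1L))
  int  <- rep(int1, C) + rep.int((0:(C - 1L)) * HpWp, rep.int(H * W, C))
  dxv <- rep(-1:1, each = 3L); dyv <- rep(-1:1, times = 3L)
  A <- outer(dxv * Hp + dyv, int1, "+")          # 9 x (H*W)
  G <- do.call(rbind, lapply(0:(C - 1L), function(cc) A + cc * HpWp))
  gidx <- as.vector(G)                           # patch row fastest, then position
  g <- list(C = C, H = H, W = W, HW = H * W, C9 = C * 9L,
            npad = C * HpWp, int = int, gidx = gidx,
            ug = sort(unique(gidx)))
  .hs_geom[[key]] <- g
  g
}

pool_geom <- function(C, H, W) {
  key <- paste("p", C, H, W, sep = "_")
  g <- .hs_geom[[key]]
  if (!is.null(g)) return(g)
  H2 <- H %/% 2L; W2 <- W %/% 2L
  # output position (y2, x2, c); input index for corner (ry, rx) in 0:1
  base <- function(ry, rx) {
    v <- as.vector(outer(seq_len(H2), seq_len(W2),
                         function(y2, x2) (2L * x2 - 2L + rx) * H + (2L * y2 - 1L + ry)))
    rep(v, C) + rep.int((0:(C - 1L)) * H * W, rep.int(H2 * W2, C))
  }
  g <- list(H2 = H2, W2 = W2, n_in = C * H * W, n_out = C * H2 * W2,
            i1 = base(0L, 0L), i2 = base(1L, 0L), i3 = base(0L, 1L), i4 = base(1L, 1L))
  .hs_geom[[key]] <- g
  g
}

# ---------------------------------------------------------------------------
# layer primitives ----------------------------------------------------------

relu <- function(x) { x[x < 0] <- 0; x }

conv_fw <- function(Wm, b, X, g, N) {
  Xp <- matrix(0, g$npad, N)
  Xp[g$int, ] <- X
  P <- Xp[g$gidx, , drop = FALSE]
  dim(P) <- c(g$C9, g$HW * N)
  Y <- Wm %*% P + b
  Cout <- nrow(Wm)
  dim(Y) <- c(Cout, g$HW, N)
  Y <- aperm(Y, c(2L, 1L, 3L))
  dim(Y) <- c(g$HW * Cout, N)
  list(Y = Y, P = P)
}

conv_bw <- function(Wm, P, dY, g, N) {
  Cout <- nrow(Wm)
  dim(dY) <- c(g$HW, Cout, N)
  dY <- aperm(dY, c(2L, 1L, 3L))
  dim(dY) <- c(Cout, g$HW * N)
  db <- rowSums(dY)
  dW <- tcrossprod(dY, P)
  dP <- crossprod(Wm, dY)
  dim(dP) <- c(g$C9 * g$HW, N)
  S <- rowsum(dP, g$gidx, reorder = TRUE)
  dXp <- matrix(0, g$npad, N)
  dXp[g$ug, ] <- S
  list(dW = dW, db = db, dX = dXp[g$int, , drop = FALSE])
}

pool_fw <- function(X, g) {
  A1 <- X[g$i1, , drop = FALSE]; A2 <- X[g$i2, , drop = FALSE]
  A3 <- X[g$i3, , drop = FALSE]; A4 <- X[g$i4, , drop = FALSE]
  Y <- pmax(A1, A2, A3, A4)
  m1 <- A1 == Y; m2 <- (A2 == Y) & !m1
  m3 <- (A3 == Y) & !(m1 | m2); m4 <- !(m1 | m2 | m3)
  list(Y = Y, m = list(m1, m2, m3, m4))
}

pool_bw <- function(dY, m, g, N) {
  dX <- matrix(0, g$n_in, N)
  dX[g$i1, ] <- dY * m[[1L]]; dX[g$i2, ] <- dY * m[[2L]]
  dX[g$i3, ] <- dY * m[[3L]]; dX[g$i4, ] <- dY * m[[4L]]
  dX
}

softmax_cols <- function(Z) {
  Z <- exp(Z - rep(apply(Z, 2L, max), each = nrow(Z)))
  Z / rep(colSums(Z), each = nrow(Z))
}

# ---------------------------------------------------------------------------
# architecture --------------------------------------------------------------

#' Architecture of the convolutional classifier
#'
#' Describes a scaled VGG-style network: `n_blocks` stacked
#' conv3x3-conv3x3-maxpool blocks, a dense ReLU layer, and a softmax output.
#' The default (3 blocks of 16/32/64 channels, 64 dense units) is a
#' desk-scale homothety of VGG-16; the full-size architecture remains
#' expressible through these fields.
#'
#' @param n_blocks number of conv-conv-pool blocks (each halves the spatial
#'   size).
#' @param channels integer vector of length `n_blocks`: output channels per
#'   block.
#' @param dense_units width of the dense hidden layer.
#' @param n_classes number of output classes (softmax width).
#' @param input_size `c(height, width)` of the (grayscale) input images.
#' @param n_trunks number of parallel convolutional trunks; `1` for a
#'   single-input network, the number of modalities for a multiple-input
#'   network whose flattened trunk features are concatenated before the
#'   dense head.
#' @return An object of class `"hs_arch"`.
#' @examples
#' hs_arch(n_blocks = 2, channels = c(8, 16), dense_units = 32, n_classes = 5,
#'         input_size = c(24, 24))
#' @export
hs_arch <- function(n_blocks = 3L, channels = c(16L, 32L, 64L),
                    dense_units = 64L, n_classes = 2L,
                    input_size = c(64L, 64L), n_trunks = 1L) {
  n_blocks <- as.integer(n_blocks)
  if (n_blocks < 1L) hs_stop("n_blocks must be >= 1", "hs_arch_error")
  if (length(channels) != n_blocks || any(channels < 1L))
    hs_stop("channels must be strictly positive and of length n_blocks", "hs_arch_error")
  if (n_classes < 2L) hs_stop("n_classes must be >= 2", "hs_arch_error")
  h <- input_size[1L]; w <- input_size[2L]
  if (h %% 2^n_blocks != 0L || w %% 2^n_blocks != 0L || min(h, w) < 2^n_blocks)
    hs_stop(sprintf("input size %dx%d not divisible by 2^%d poolings", h, w, n_blocks),
            "hs_arch_error")
  structure(list(n_blocks = n_blocks, channels = as.integer(channels),
                 dense_units = as.integer(dense_units),
                 n_classes = as.integer(n_classes),
                 input_size = as.integer(c(h, w)),
                 n_trunks = as.integer(n_trunks)),
            class = "hs_arch")
}

arch_feat_dim <- function(arch) {
  h <- arch$input_size[1L] %/% 2L^arch$n_blocks
  w <- arch$input_size[2L] %/% 2L^arch$n_blocks
  arch$channels[arch$n_blocks] * h * w
}

trunk_param_names <- function(arch) {
  unlist(lapply(seq_len(arch$n_trunks), function(k)
    unlist(lapply(seq_len(arch$n_blocks), function(b)
      sprintf("t%d.b%d.%s", k, b, c("W1", "b1", "W2", "b2"))))))
}

#' Build an untrained convolutional classifier
#'
#' Initialises all parameters from a seeded He-normal scheme; identical
#' `arch` and `seed` give bit-identical initial parameters.
#'
#' @param arch an [hs_arch()] description.
#' @param seed integer seed for weight initialisation.
#' @return An object of class `"hs_cnn"` (untrained).
#' @examples
#' m <- hs_cnn(hs_arch(n_blocks = 1, channels = 4, dense_units = 8,
#'                     n_classes = 2, input_size = c(8, 8)), seed = 1)
#' @export
hs_cnn <- function(arch, seed = 1L) {
  stopifnot(inherits(arch, "hs_arch"))
  params <- with_seed(seed, {
    p <- list()
    for (k in seq_len(arch$n_trunks)) {
      cin <- 1L
      for (b in seq_len(arch$n_blocks)) {
        cout <- arch$channels[b]
        p[[sprintf("t%d.b%d.W1", k, b)]] <-
          matrix(stats::rnorm(cout * cin * 9L, 0, sqrt(2 / (cin * 9L))), cout, cin * 9L)
        p[[sprintf("t%d.b%d.b1", k, b)]] <- numeric(cout)
        p[[sprintf("t%d.b%d.W2", k, b)]] <-
          matrix(stats::rnorm(cout * cout * 9L, 0, sqrt(2 / (cout * 9L))), cout, cout * 9L)
        p[[sprintf("t%d.b%d.b2", k, b)]] <- numeric(cout)
        cin <- cout
      }
    }
    fd <- arch_feat_dim(arch) * arch$n_trunks
    p[["head.W1"]] <- matrix(stats::rnorm(arch$dense_units * fd, 0, sqrt(2 / fd)),
                             arch$dense_units, fd)
    p[["head.b1"]] <- numeric(arch$dense_units)
    p[["head.W2"]] <- matrix(stats::rnorm(arch$n_classes * arch$dense_units, 0,
                                          sqrt(1 / arch$dense_units)),
                             arch$n_classes, arch$dense_units)
    p[["head.b2"]] <- numeric(arch$n_classes)
    p
  })
  structure(list(arch = arch, params = params, class_order = NULL,
                 trained = FALSE, training_log = NULL),
            class = "hs_cnn")
}

# ---------------------------------------------------------------------------
# forward / backward --------------------------------------------------------

# xs: list of (npix x N) matrices, one per trunk
net_forward <- function(params, arch, xs, cache = FALSE) {
  N <- ncol(xs[[1L]])
  caches <- if (cache) vector("list", arch$n_trunks)
  feats <- vector("list", arch$n_trunks)
  for (k in seq_len(arch$n_trunks)) {
    Z <- xs[[k]]
    h <- arch$input_size[1L]; w <- arch$input_size[2L]; cin <- 1L
    blocks <- if (cache) vector("list", arch$n_blocks)
    for (b in seq_len(arch$n_blocks)) {
      cout <- arch$channels[b]
      g1 <- conv_geom(cin, h, w)
      c1 <- conv_fw(params[[sprintf("t%d.b%d.W1", k, b)]],
                    params[[sprintf("t%d.b%d.b1", k, b)]], Z, g1, N)
      A1 <- relu(c1$Y)
      g2 <- conv_geom(cout, h, w)
      c2 <- conv_fw(params[[sprintf("t%d.b%d.W2", k, b)]],
                    params[[sprintf("t%d.b%d.b2", k, b)]], A1, g2, N)
      A2 <- relu(c2$Y)
      gp <- pool_geom(cout, h, w)
      pl <- pool_fw(A2, gp)
      if (cache)
        blocks[[b]] <- list(P1 = c1$P, A1 = A1, P2 = c2$P, A2 = A2,
                            pm = pl$m, g1 = g1, g2 = g2, gp = gp)
      Z <- pl$Y
      h <- h %/% 2L; w <- w %/% 2L; cin <- cout
    }
    feats[[k]] <- Z
    if (cache) caches[[k]] <- blocks
  }
  feats <- if (arch$n_trunks > 1L) do.call(rbind, feats) else feats[[1L]]
  H1 <- relu(params[["head.W1"]] %*% feats + params[["head.b1"]])
  logits <- params[["head.W2"]] %*% H1 + params[["head.b2"]]
  out <- list(logits = logits, probs = softmax_cols(logits))
  if (cache) { out$feats <- feats; out$H1 <- H1; out$caches <- caches }
  out
}

# dLogits: K x N gradient; fw: cached forward pass
net_backward <- function(params, arch, fw, dLogits) {
  N <- ncol(dLogits)
  gr <- list()
  gr[["head.W2"]] <- tcrossprod(dLogits, fw$H1)
  gr[["head.b2"]] <- rowSums(dLogits)
  dH1 <- crossprod(params[["head.W2"]], dLogits)
  dH1[fw$H1 <= 0] <- 0
  gr[["head.W1"]] <- tcrossprod(dH1, fw$feats)
  gr[["head.b1"]] <- rowSums(dH1)
  dfeats <- crossprod(params[["head.W1"]], dH1)
  fd <- arch_feat_dim(arch)
  for (k in seq_len(arch$n_trunks)) {
    dZ <- dfeats[((k - 1L) * fd + 1L):(k * fd), , drop = FALSE]
    for (b in rev(seq_len(arch$n_blocks))) {
      bc <- fw$caches[[k]][[b]]
      dA2 <- pool_bw(dZ, bc$pm, bc$gp, N)
      dA2[bc$A2 <= 0] <- 0
      r2 <- conv_bw(params[[sprintf("t%d.b%d.W2", k, b)]], bc$P2, dA2, bc$g2, N)
      gr[[sprintf("t%d.b%d.W2", k, b)]] <- r2$dW
      gr[[sprintf("t%d.b%d.b2", k, b)]] <- r2$db
      dA1 <- r2$dX
      dA1[bc$A1 <= 0] <- 0
      r1 <- conv_bw(params[[sprintf("t%d.b%d.W1", k, b)]], bc$P1, dA1, bc$g1, N)
      gr[[sprintf("t%d.b%d.W1", k, b)]] <- r1$dW
      gr[[sprintf("t%d.b%d.b1", k, b)]] <- r1$db
      dZ <- r1$dX
    }
  }
  gr
}

# coerce user input (matrix, 3-d array, or list per trunk) to trunk list
as_trunk_input <- function(x, arch) {
  if (is.list(x)) xs <- x else xs <- list(x)
  if (length(xs) != arch$n_trunks)
    hs_stop(sprintf("expected %d input matrices, got %d", arch$n_trunks, length(xs)),
            "hs_input_error")
  npix <- prod(arch$input_size)
  xs <- lapply(xs, function(m) {
    if (is.array(m) && length(dim(m)) == 3L) m <- matrix(m, nrow = prod(dim(m)[1:2]))
    if (!is.matrix(m)) m <- matrix(m, ncol = 1L)
    if (nrow(m) != npix)
      hs_stop(sprintf("image size mismatch: expected %d pixels, got %d", npix, nrow(m)),
              "hs_input_error")
    m
  })
  xs
}
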