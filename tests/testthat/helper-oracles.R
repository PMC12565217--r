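# Independent brute-force oracles used to validate the vectorised
# implementations. These are written in the most literal way possible
# (explicit per-pixel loops, set arithmetic on coordinate pairs) and share
# no code with the package internals.

# reflect (symmetric) index, 1-based
refl <- function(i, n) {
  period <- 2 * n
  j <- ((i - 1) %% period + period) %% period
  ifelse(j < n, j + 1, period - j)
}

# dense 2-D convolution with reflect padding: each output pixel is the
# literal sum of kernel * window over an explicitly padded copy
bruteConv <- function(m, kernel) {
  kh <- nrow(kernel); kw <- ncol(kernel)
  ph <- (kh - 1) / 2; pw <- (kw - 1) / 2
  h <- nrow(m); w <- ncol(m)
  mp <- m[refl(seq(1 - ph, h + ph), h), refl(seq(1 - pw, w + pw), w)]
  out <- matrix(0, h, w)
  for (i in seq_len(h)) for (j in seq_len(w))
    out[i, j] <- sum(kernel * mp[i:(i + kh - 1), j:(j + kw - 1)])
  out
}

# exact median filter via sorting each window
bruteMedian <- function(m, window = 3) {
  p <- (window - 1) / 2
  h <- nrow(m); w <- ncol(m)
  out <- matrix(0, h, w)
  for (i in seq_len(h)) for (j in seq_len(w)) {
    vals <- numeric(0)
    for (a in -p:p) for (b in -p:p)
      vals <- c(vals, m[refl(i + a, h), refl(j + b, w)])
    out[i, j] <- sort(vals)[(window * window + 1) / 2]
  }
  out
}

# overlap metrics from explicit coordinate sets
coordSet <- function(mask) {
  idx <- which(mask)
  idx
}
bruteDice <- function(p, t) {
  sp <- coordSet(p); st <- coordSet(t)
  if (length(sp) + length(st) == 0) return(1)
  2 * length(intersect(sp, st)) / (length(sp) + length(st))
}
bruteJaccard <- function(p, t) {
  sp <- coordSet(p); st <- coordSet(t)
  u <- length(union(sp, st))
  if (u == 0) return(1)
  length(intersect(sp, st)) / u
}

# directed distances by explicit double loop over point rows
bruteDirected <- function(A, B) {
  out <- numeric(nrow(A))
  for (i in seq_len(nrow(A))) {
    best <- Inf
    for (j in seq_len(nrow(B)))
      best <- min(best, sqrt(sum((A[i, ] - B[j, ])^2)))
    out[i] <- best
  }
  out
}
bruteHausdorff <- function(A, B, mode = "max") {
  dab <- bruteDirected(A, B); dba <- bruteDirected(B, A)
  switch(mode,
         max = max(c(max(dab), max(dba))),
         hd95 = max(quantile(dab, 0.95, names = FALSE),
                    quantile(dba, 0.95, names = FALSE)),
         assd = (sum(dab) + sum(dba)) / (length(dab) + length(dba)))
}

# global F-measure from counts
bruteF <- function(p, t) {
  tp <- sum(p & t); fp <- sum(p & !t); fn <- sum(!p & t)
  if (tp + fp + fn == 0) return(1)
  prec <- if (tp + fp == 0) 0 else tp / (tp + fp)
  rec <- if (tp + fn == 0) 0 else tp / (tp + fn)
  if (prec + rec == 0) return(0)
  2 * prec * rec / (prec + rec)
}

randomImage <- function(seed, h, w = h) {
  set.seed(seed)
  matrix(runif(h * w), h, w)
}
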