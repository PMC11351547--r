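# Brute-force oracles, implemented independently of the package internals.

# Transformed-box oracle: rasterize the box as a filled rectangle, map every
# output pixel center through the transform's analytic inverse, test
# membership in the original rectangle (half-open, continuous), and take the
# bounding box of the surviving pixels.
oracleTransformedBox <- function(box, w, h, technique, p) {
  cx <- w / 2; cy <- h / 2
  ox <- matrix(rep(seq_len(w) - 0.5, each = h), h, w)
  oy <- matrix(rep(seq_len(h) - 0.5, times = w), h, w)
  if (technique == "translation") {
    sx <- ox - round(p * w); sy <- oy - round(p * h)
  } else if (technique == "zoom") {
    sx <- cx + (ox - cx) / p; sy <- cy + (oy - cy) / p
  } else if (technique == "rotation") {
    th <- p * pi / 180
    dx <- ox - cx; dy <- oy - cy
    sx <- cx + cos(th) * dx + sin(th) * dy
    sy <- cy - sin(th) * dx + cos(th) * dy
  } else {
    stop("unknown technique in oracle")
  }
  ins <- sx >= box@xmin & sx < box@xmax & sy >= box@ymin & sy < box@ymax
  if (!any(ins)) return(NULL)
  idx <- which(ins, arr.ind = TRUE)
  c(xmin = min(idx[, 2L]) - 1L, ymin = min(idx[, 1L]) - 1L,
    xmax = max(idx[, 2L]), ymax = max(idx[, 1L]))
}

# Random geometric-transform test cases whose transformed box stays strictly
# inside the canvas (so clipping never enters the comparison).  Deterministic
# for a given seed.
randomBoxCases <- function(n, seed) {
  set.seed(seed)
  cases <- list()
  while (length(cases) < n) {
    w <- sample(60:100, 1L); h <- sample(60:100, 1L)
    bw <- sample(8:20, 1L); bh <- sample(8:20, 1L)
    x0 <- sample(seq(round(w / 3), round(w / 2)), 1L)
    y0 <- sample(seq(round(h / 3), round(h / 2)), 1L)
    box <- BoundingBox(x0, y0, x0 + bw, y0 + bh)
    technique <- sample(c("translation", "zoom", "rotation"), 1L)
    p <- switch(technique,
                translation = runif(1, -0.15, 0.15),
                zoom = runif(1, 0.6, 1.5),
                rotation = runif(1, -10, 10))
    o <- oracleTransformedBox(box, w, h, technique, p)
    if (is.null(o) || o["xmin"] == 0 || o["ymin"] == 0 ||
        o["xmax"] == w || o["ymax"] == h)
      next
    cases[[length(cases) + 1L]] <-
      list(box = box, w = w, h = h, technique = technique, p = p, oracle = o)
  }
  cases
}

# IoU by counting integer pixels contained in each half-open box.
oraclePixelIoU <- function(a, b) {
  inBox <- function(box, x, y)
    x >= box@xmin & x < box@xmax & y >= box@ymin & y < box@ymax
  xs <- 0:(max(a@xmax, b@xmax) - 1L)
  ys <- 0:(max(a@ymax, b@ymax) - 1L)
  g <- expand.grid(x = xs, y = ys)
  ia <- inBox(a, g$x, g$y); ib <- inBox(b, g$x, g$y)
  sum(ia & ib) / sum(ia | ib)
}
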