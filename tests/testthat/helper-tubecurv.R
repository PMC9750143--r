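# shared fixtures built in code

quiet_gt <- function(...) {
  imaging_ground_truth(noise_model = list(type = "none"), ...)
}

# finite-difference shape-operator oracle: uses only membrane_height(),
# independently of the analytic-derivative path it cross-checks
fd_mean_curvature <- function(surface, x, y, h = 1e-3) {
  H <- function(xx, yy) membrane_height(surface, xx, yy)
  vapply(seq_along(x), function(i) {
    xx <- x[i]; yy <- y[i]
    hx <- (H(xx + h, yy) - H(xx - h, yy)) / (2 * h)
    hy <- (H(xx, yy + h) - H(xx, yy - h)) / (2 * h)
    hxx <- (H(xx + h, yy) - 2 * H(xx, yy) + H(xx - h, yy)) / h^2
    hyy <- (H(xx, yy + h) - 2 * H(xx, yy) + H(xx, yy - h)) / h^2
    hxy <- (H(xx + h, yy + h) - H(xx + h, yy - h) -
              H(xx - h, yy + h) + H(xx - h, yy - h)) / (4 * h^2)
    -((1 + hy^2) * hxx - 2 * hx * hy * hxy + (1 + hx^2) * hyy) /
      (2 * (1 + hx^2 + hy^2)^1.5)
  }, 0)
}

# a hand-built frame with rectangular structures of known constant value,
# for arithmetic checks independent of the renderer
block_frame <- function(mem_bg = 10, mem_tube = 100, mem_guv = 200,
                        prot_bg = 0, prot_tube = 40, prot_guv = 20) {
  mem <- matrix(mem_bg, 60, 120)
  prot <- matrix(prot_bg, 60, 120)
  mem[28:32, 70:110] <- mem_tube; prot[28:32, 70:110] <- prot_tube
  mem[10:50, 10:20] <- mem_guv; prot[10:50, 10:20] <- prot_guv
  structure(
    list(membrane = mem, protein = prot, pixel_size = 100, timestamp = 0,
         hints = list(tube = c(60, 115, 20, 40), guv = c(5, 25, 5, 55)),
         truth = NULL),
    class = "tube_frame"
  )
}

iou <- function(a, b, rect) {
  w <- matrix(FALSE, nrow(a), ncol(a))
  w[rect[3]:rect[4], rect[1]:rect[2]] <- TRUE
  sum(a & b & w) / sum((a | b) & w)
}
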