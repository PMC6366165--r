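# Brute-force flood-fill labelling used as an independent oracle for
# label_patches(); plain R, breadth-first over an explicit queue.
flood_fill_labels <- function(mask, connectivity = 8L) {
  H <- nrow(mask); W <- ncol(mask)
  lab <- matrix(0L, H, W)
  sizes <- integer(0)
  nb <- if (connectivity == 8L)
    cbind(c(-1, -1, -1, 0, 0, 1, 1, 1), c(-1, 0, 1, -1, 1, -1, 0, 1))
  else cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
  nxt <- 0L
  for (i in seq_len(H)) for (j in seq_len(W)) {
    if (!mask[i, j] || lab[i, j] > 0L) next
    nxt <- nxt + 1L
    queue <- list(c(i, j))
    lab[i, j] <- nxt
    sz <- 0L
    while (length(queue)) {
      cur <- queue[[1]]; queue <- queue[-1]
      sz <- sz + 1L
      for (k in seq_len(nrow(nb))) {
        ni <- cur[1] + nb[k, 1]; nj <- cur[2] + nb[k, 2]
        if (ni < 1 || ni > H || nj < 1 || nj > W) next
        if (mask[ni, nj] && lab[ni, nj] == 0L) {
          lab[ni, nj] <- nxt
          queue[[length(queue) + 1L]] <- c(ni, nj)
        }
      }
    }
    sizes[nxt] <- sz
  }
  list(patch_id = lab, patch_sizes = sizes)
}

# trait set used by corridor oracle tests: unbounded perception, no foraging
corridor_traits <- function(m, speed = 1, T = 100) {
  trait_set(speed = speed, perceptual_range = T * speed + 2, mortality = m,
            min_area = 1, foraging_tendency = 0, validate = FALSE)
}
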