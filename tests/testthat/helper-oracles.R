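# Independent reference implementations used to validate package internals.

# brute-force TFCE: literal threshold sum with an R flood-fill labeller
tfce_oracle <- function(map, H = 2, E = 0.5, step = 0.1, connectivity = 6) {
  dims <- dim(map)
  out <- array(0, dims)
  mx <- max(map)
  if (mx <= 0) return(out)
  hs <- seq(step, mx + step / 2, by = step)
  hs <- hs[hs <= mx + 1e-12]
  for (h in hs) {
    lab <- label_oracle(map >= h, connectivity)
    if (max(lab) == 0) next
    ext <- tabulate(lab)
    idx <- which(lab > 0)
    out[idx] <- out[idx] + ext[lab[idx]]^E * h^H * step
  }
  out
}

# queue-based connected components on a logical 3-D array
label_oracle <- function(mask, connectivity = 6) {
  dims <- dim(mask)
  off <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  m <- abs(off$dx) + abs(off$dy) + abs(off$dz)
  off <- off[m > 0 & m <= switch(as.character(connectivity),
                                 "6" = 1, "18" = 2, "26" = 3), ]
  lab <- array(0L, dims)
  nxt <- 0L
  for (v in which(mask)) {
    if (lab[v] > 0L) next
    nxt <- nxt + 1L
    queue <- v
    lab[v] <- nxt
    while (length(queue)) {
      cur <- queue[1]; queue <- queue[-1]
      co <- arrayInd(cur, dims)
      for (r in seq_len(nrow(off))) {
        nb <- co + c(off$dx[r], off$dy[r], off$dz[r])
        if (any(nb < 1) || any(nb > dims)) next
        i <- nb[1] + dims[1] * (nb[2] - 1 + dims[2] * (nb[3] - 1))
        if (mask[i] && lab[i] == 0L) {
          lab[i] <- nxt
          queue <- c(queue, i)
        }
      }
    }
  }
  lab
}

# WAIC by the definition, loops and all
waic_oracle <- function(ll) {
  lppd <- sum(log(colMeans(exp(ll))))
  p <- sum(apply(ll, 2, var))
  -2 * (lppd - p)
}

# small behavioral dataset shared across fit tests
make_small_study <- function(n_participants = 10, seed = 42,
                             group = group_parameters()) {
  design <- generate_design(108, seed = 1)
  behav <- simulate_participants(group, n_participants, design, seed = seed)
  list(design = design, behavior = behav, group = group)
}
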