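# Shared fixtures, built in code at load time. Kept small so the whole
# suite stays desk-scale.

fx_concepts <- make_concept_set(seed = 1)

# Pad a simulated run with n_trim lead-in volumes (copies of the first
# volume) and shift onsets accordingly, so prepare_examples() can trim.
pad_run <- function(run, n_trim = 10L) {
  pad <- array(run$data[, , , 1], dim = c(run$grid$shape, n_trim))
  bold_run(array(c(pad, run$data),
                 dim = c(run$grid$shape, n_trim + dim(run$data)[4])),
           run$grid, tr = run$tr, run_id = run$run_id)
}

shift_events <- function(events, n_trim = 10L, tr = 0.85) {
  events$onset <- events$onset + n_trim * tr
  events
}

# One small simulated subject with a strong class pattern on desirability,
# prepared into an example set; reused by several test files.
fx_small_subject <- local({
  grid <- make_volume_grid(c(10L, 10L, 10L))
  spec <- make_signal_spec(grid, dimension = "desirability",
                           effect_scale = 3, noise_sd = 1, seed = 11)
  sim <- simulate_subject(fx_concepts, grid, spec, n_runs = 2L, seed = 7)
  runs <- lapply(sim$runs, pad_run)
  events <- lapply(sim$events, shift_events)
  es <- prepare_examples(runs, events, n_trim = 10L)
  list(grid = grid, spec = spec, sim = sim, example_set = es)
})

# Brute-force connected components in plain R (flood fill over a logical
# 3D array); independent oracle for the compiled labelling.
r_label_components <- function(keep, connectivity = 26) {
  d <- dim(keep)
  lab <- array(0L, dim = d)
  nb <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  nb <- nb[rowSums(abs(nb)) > 0, ]
  if (connectivity == 6) nb <- nb[rowSums(abs(nb)) == 1, ]
  cur <- 0L
  for (i in which(keep)) {
    if (lab[i] != 0L) next
    cur <- cur + 1L
    queue <- i
    lab[i] <- cur
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      co <- arrayInd(v, d)
      for (r in seq_len(nrow(nb))) {
        cc <- co + nb[r, ]
        if (any(cc < 1) || any(cc > d)) next
        j <- cc[1] + d[1] * (cc[2] - 1 + d[2] * (cc[3] - 1))
        if (keep[j] && lab[j] == 0L) {
          lab[j] <- cur
          queue <- c(queue, j)
        }
      }
    }
  }
  lab
}

# Brute-force TFCE Riemann sum in R, using r_label_components.
r_tfce <- function(map, E = 0.5, H = 2, dh = 0.1, connectivity = 26) {
  out <- array(0, dim = dim(map))
  mx <- max(map)
  if (mx <= 0) return(out)
  for (h in seq(dh, mx + 1e-12, by = dh)) {
    lab <- r_label_components(map >= h, connectivity)
    sizes <- tabulate(lab)
    sup <- lab > 0
    out[sup] <- out[sup] + sizes[lab[sup]]^E * h^H * dh
  }
  out
}
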