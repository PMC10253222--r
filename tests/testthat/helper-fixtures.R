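# Small fixtures shared across test files.  Everything is generated in code;
# sizes are kept small so the whole suite runs quickly on one CPU.

# a compact phantom specification for unit tests (48 x 48 x 12 voxels)
tiny_phantom_spec <- function(seed = 0L, n_cases = 2L) {
  phantom_spec(seed = seed, n_cases = n_cases, grid = c(48L, 48L, 12L))
}

n_slices_of <- function(volume) dim(volume$pixels)[3]

# a deterministic random case volume (not anatomically meaningful)
random_volume <- function(seed, W = 60L, H = 60L, n = 4L, vmax = 4071L) {
  set.seed(seed)
  px <- array(sample.int(vmax + 1L, W * H * n, replace = TRUE) - 1L,
              c(W, H, n))
  case_volume(px, paste0("rand_", seed), seq_len(n) * 5)
}

# a deterministic random landmark table with in-bounds coordinates
random_table <- function(seed, case_id = paste0("case_", seed),
                         frame = 512, zmax = 400) {
  set.seed(seed)
  landmark_table(cbind(runif(16, 10, frame - 10), runif(16, 10, frame - 10),
                       runif(16, 0, zmax)), case_id)
}
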