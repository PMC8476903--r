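# Shared fixtures, memoized so expensive phantoms are built once per run.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, .fixture_env))
    assign(key, force(expr), .fixture_env)
  get(key, .fixture_env)
}

# small noise-free phantom for geometric/collector tests
tiny_case <- function() memo("tiny_case", {
  generate_case(phantom_config(shape = c(24, 24, 12), spacing = c(16, 16, 16),
                               noise_sd = 0, seed = 11))
})

# moderately resolved phantom with noise, for IO round-trips
small_case <- function() memo("small_case", {
  generate_case(phantom_config(shape = c(32, 32, 16), spacing = c(8, 8, 8),
                               noise_sd = 5, seed = 12))
})

# full-resolution phantom (4 mm voxels) for voxelization-accuracy checks
hires_case <- function() memo("hires_case", {
  generate_case(phantom_config(noise_sd = 0, seed = 12))
})

# rotationally symmetric phantom (all structures are centered or dose-inert)
symmetric_case <- function() memo("symmetric_case", {
  organs <- list(
    body      = list(center = c(0, 0, 0), semi = c(100, 100, 60), hu = 40),
    TLV       = list(center = c(0, 0, 0), semi = c(50, 50, 40), hu = 60),
    PGTV      = list(center = c(0, 0, 0), semi = c(20, 20, 20), hu = 55),
    duodenum  = list(center = c(0, 0, -40), semi = c(8, 8, 8), hu = 30),
    stomach   = list(center = c(0, 0, 40), semi = c(8, 8, 8), hu = 30),
    esophagus = list(center = c(0, 0, 0), semi = c(5, 5, 5), hu = 30),
    heart     = list(center = c(0, 0, 30), semi = c(6, 6, 6), hu = 45),
    spleen    = list(center = c(0, 0, -30), semi = c(6, 6, 6), hu = 50))
  generate_case(phantom_config(shape = c(32, 32, 16), spacing = c(8, 8, 8),
                               noise_sd = 0, seed = 13, tumor_offset = c(0, 0, 0),
                               organs = organs))
})

# reduced network spec matched to a (n_angles x 25 x 9) x n_bins tensor
reduced_spec <- function(n_angles = 24, n_bins = 50, hidden = 64)
  baods_netspec(n_angles = n_angles, n_bins = n_bins,
                conv_channels = c(3, 9), pool_after = c(TRUE, FALSE),
                hidden = hidden)

# Recovery cohort: 8 phantoms whose anatomy is rigidly rotated 0..35 deg in
# 5 deg steps. Three tangentially elongated OAR blocks ring the tumor,
# leaving three narrow beam corridors ~120 deg apart, so the geometric
# optimum is sharp and all three reference angles vary continuously with
# the rotation (an identifiable recovery target). Noise-free so the
# between-case input differences are purely geometric.
recovery_cohort <- function() memo("recovery_cohort", {
  tum <- c(-37, -7, 9)
  blk <- function(a) list(center = c(tum[1] + 52 * cos(a * pi / 180),
                                     tum[2] + 52 * sin(a * pi / 180),
                                     tum[3]),
                          semi = c(66, 18, 26), rot = a + 90)
  blocks <- list(stomach = blk(90), duodenum = blk(210), heart = blk(330))
  rots <- seq(0, 35, by = 5)
  lapply(seq_along(rots), function(i)
    generate_case(phantom_config(rotation_deg = rots[i], seed = 100 + i,
                                 noise_sd = 0, organs = blocks)))
})

# feature tensor + reference score pairs for the reduced training setup
reduced_pair <- function(case, angle_step = 15, n_bins = 50, sigma = 5) {
  list(x = build_feature_tensor(case, angle_step = angle_step,
                                n_bins = n_bins),
       y = make_sbeam(case$clinical_angles, sigma = sigma),
       case_id = case$case_id)
}
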