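# shared fixtures, built once per test run

default_scheme <- build_scheme(30, c(1000, 2000), 5)

# prolate ("cigar") diffusion tensor with a mixture-derived kurtosis tensor
# rescaled so that MK over the acquisition directions is exactly 0.9
cigar_truth <- local({
  mix <- kt_from_gaussian_mixture(
    list(diag(c(1.7, 0.3, 0.3)), diag(c(0.9, 0.15, 0.15))), c(0.5, 0.5))
  mix$d6 <- dt_pack(diag(c(1.7, 0.3, 0.3)))
  mix$w15 <- scale_w_to_mk(mix$d6, mix$w15,
                           default_scheme$unique_directions, 0.9)
  mix$S0 <- 100
  mix
})

# draw one random physically valid voxel (mixture of 2 rotated Gaussian
# compartments, kurtosis inside the model validity range at b_max)
random_valid_voxel <- function() random_dki_voxel(default_scheme)

random_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  dkidisc:::quaternion_rotation(q)
}

# tiny cohort spec for fast statistical tests
small_cohort <- function(seed = 1L) generate_cohort(cohort_spec(seed = seed))
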