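## shared fixtures: the calibrated human-shear parameter set, a standard
## aligned frame, and small geometries reused across tests

ref_params <- function(...) passive_params(...)

ref_param_vec <- c(a = 1.05, b = 7.542, a_f = 3.465, b_f = 14.472,
                   a_s = 0.481, b_s = 12.548, a_fs = 0.283, b_fs = 3.088)

std_frame <- function() local_frame(c(1, 0, 0), c(0, 1, 0))

## random deformation gradient with J in [0.9, 1.1] and moderate distortion
random_F <- function() {
  F <- diag(3) + matrix(stats::rnorm(9, sd = 0.06), 3, 3)
  J <- det(F)
  if (J <= 0) return(random_F())
  F * (stats::runif(1, 0.9, 1.1) / J)^(1 / 3)
}

## total strain energy density (isochoric + volumetric) for FD oracles
total_energy <- function(F, frame, params, h = 1) {
  st <- deformation_state(F, frame)
  isochoric_energy(st, frame, params, h) + volumetric_energy(st$J, params$D)
}

small_lv <- function(...) preset_geometry("normal", "lv", ...)

thick_sphere_geom <- function(A = 10, B = 14)
  ventricle_geometry(A, A, B, B, z_base = 2 * B)

noiseless_shear_data <- function(params = ref_params(),
                                 gammas = seq(0.025, 0.5, length.out = 20))
  gen_shear_data(params, gammas, noise_sd = 0, seed = 1)
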