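# Shared phantom fixtures. All are built in code at test time.

# Desk-scale dynamic rat-lung phantom used by the end-to-end recovery tests:
# the spec's desk geometry (matrix 64, 4 slices, ~4000 profiles) at the
# study's effective repetition time (114 ms), compartment peak enhancements
# at bin-interval midpoints.
desk_phantom_spec <- function(seed = 11, modulation = NULL) {
  ent <- list(
    phantom_entry("body", "body", list(ellipse(0, -1, 21, 15)),
                  t1 = 1600, pd = 0.7, peak_re = 0.3,
                  tau_in = 6, tau_out = 60),
    phantom_entry("parenchyma", "parenchyma",
                  list(ellipse(-8.5, 0, 6.2, 9.2, theta = 8),
                       ellipse(8.5, 0, 6.2, 9.2, theta = -8)),
                  t1 = 1100, pd = 0.3, peak_re = 1.5,
                  tau_in = 6, tau_out = 60),
    phantom_entry("lesion", "lesion",
                  list(ellipse(7.8, -2.5, 3.0, 4.0, theta = -20)),
                  t1 = 1300, pd = 0.8, peak_re = 2.5,
                  tau_in = 6, tau_out = 80),
    phantom_entry("vessels", "vessel",
                  list(ellipse(-5.2, 1.5, 1.3, 2.8, theta = 25),
                       ellipse(5.2, 1.5, 1.3, 2.8, theta = -25)),
                  t1 = 1900, pd = 1.0, peak_re = 3.5,
                  tau_in = 5, tau_out = 70))
  phantom_spec(ent, matrix_size = 64, n_slices = 4, tr_profile = 0.0285,
               t_inj = 342, duration = 456, seed = seed,
               modulation = modulation)
}

# small static phantom (no enhancement) for drift/background tests
static_phantom_spec <- function(m = 32, n_slices = 1, seed = 3,
                                noise_rel = 5e-4, modulation = NULL,
                                tr_profile = 0.114) {
  ent <- list(
    phantom_entry("body", "body", list(ellipse(0, -1, 21, 15)),
                  t1 = 1600, pd = 0.7),
    phantom_entry("parenchyma", "parenchyma",
                  list(ellipse(-8.5, 0, 6.2, 9.2),
                       ellipse(8.5, 0, 6.2, 9.2)),
                  t1 = 1100, pd = 0.3))
  phantom_spec(ent, matrix_size = m, n_slices = n_slices,
               tr_profile = tr_profile, t_inj = 1e6, duration = 100,
               noise_rel = noise_rel, seed = seed, modulation = modulation)
}

# small lesion-bearing phantom (no vessels) for baseline morphometry
lesion_phantom_spec <- function(seed = 9, with_lesion = TRUE) {
  ent <- list(
    phantom_entry("body", "body", list(ellipse(0, -1, 21, 15)),
                  t1 = 1600, pd = 0.7),
    phantom_entry("parenchyma", "parenchyma",
                  list(ellipse(-8.5, 0, 6.2, 9.2, theta = 8),
                       ellipse(8.5, 0, 6.2, 9.2, theta = -8)),
                  t1 = 1100, pd = 0.3))
  if (with_lesion)
    ent <- c(ent, list(
      phantom_entry("lesion", "lesion",
                    list(ellipse(7.8, -2, 3.4, 4.2, theta = -20)),
                    t1 = 1300, pd = 0.8)))
  phantom_spec(ent, matrix_size = 48, n_slices = 2, tr_profile = 0.057,
               t_inj = 1e6, duration = 100, seed = seed)
}

# cache expensive fixtures across test files within one run
.fixture_env <- new.env(parent = emptyenv())
fixture <- function(name, expr) {
  if (!exists(name, envir = .fixture_env))
    assign(name, expr, envir = .fixture_env)
  get(name, envir = .fixture_env)
}
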