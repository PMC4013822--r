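# Shared phantom builders for the test suite. All fixtures are generated in
# code; nothing is read from disk.

# Flat, piecewise-constant, full-span phantom: every quantity is exactly
# recoverable (surface row 100, thickness 70 px).
flat_phantom <- function(shape = c(300, 64, 4), surface = 100, thick = 70,
                         levels = list(background = 10, enamel = 200, dentine = 80),
                         strength = 0, seed = 1) {
  phantom_params(shape = shape, levels = levels,
                 surface_fun = function(n, i, shape) rep(surface, length(n)),
                 thickness_fun = function(n, i, shape) rep(thick, length(n)),
                 speckle = list(model = "rayleigh", strength = strength),
                 seed = seed)
}

# Piecewise-constant phantom with an elliptical footprint: constant
# thickness inside the tooth, pure background outside, so the projection has
# contrast for ROI extraction while every defined thickness equals `thick`.
ellipse_flat_phantom <- function(shape = c(300, 64, 36), surface = 100,
                                 thick = 70, strength = 0, seed = 1) {
  N <- shape[2]; I <- shape[3]
  phantom_params(shape = shape,
                 levels = list(background = 10, enamel = 200, dentine = 80),
                 surface_fun = function(n, i, shape) rep(surface, length(n)),
                 thickness_fun = function(n, i, shape) {
                   e2 <- ((n - (N + 1) / 2) / (0.42 * N))^2 +
                     ((i - (I + 1) / 2) / (0.42 * I))^2
                   ifelse(e2 <= 1, thick, 0)
                 },
                 speckle = list(model = "rayleigh", strength = strength),
                 seed = seed)
}

# Registration phantom: strongly textured surface, tooth footprint small
# enough that every transform in the search range keeps the whole tooth in
# the field of view (so the criterion optimum is unambiguous).
reg_phantom <- function(seed = 5) {
  phantom_params(
    shape = c(80, 200, 150), seed = seed,
    speckle = list(model = "rayleigh", strength = 0),
    surface_fun = function(n, i, shape)
      22 + 6 * ((n - 100.5) / 100)^2 + 4 * ((i - 75.5) / 75)^2 +
      4 * n / 200 + 3 * i / 150 +
      5 * sin(2 * pi * n / 11) + 4 * sin(2 * pi * i / 9 + 1) +
      3 * sin(2 * pi * (n + i) / 7),
    thickness_fun = function(n, i, shape) {
      e2 <- ((n - 100.5) / 50)^2 + ((i - 75.5) / 27)^2
      ifelse(e2 <= 1, 20 * (0.6 + 0.4 * sqrt(pmax(0, 1 - e2))), 0)
    })
}

# Seven-stage phantom with constant in-footprint thickness (730 um at
# 5 um/px) so that planted mean deltas are exact by construction.
stage_phantom_params <- function(seed = 2) {
  phantom_params(shape = c(360, 128, 48), seed = seed,
                 speckle = list(model = "rayleigh", strength = 0),
                 thickness_fun = function(n, i, shape) {
                   e2 <- ((n - 64.5) / 55)^2 + ((i - 24.5) / 21)^2
                   ifelse(e2 <= 1, 146, 0)
                 })
}

table1_means <- c(730, 650, 295, 560, 80, 455, 605)
table1_deltas <- c(0, -80, -435, -170, -650, -275, -125)

# Full printed 7x7 stage-difference matrix (micrometres).
table2_matrix <- matrix(c(
    0,  -80, -435, -170, -650, -275, -125,
   80,    0, -355,  -90, -570, -195,  -45,
  435,  355,    0,  265, -215,  160,  310,
  170,   90, -265,    0, -480, -105,   45,
  650,  570,  215,  480,    0,  375,  525,
  275,  195, -160,  105, -375,    0,  150,
  125,   45, -310,  -45, -525, -150,    0), 7, 7, byrow = TRUE)

truth_thickness_or_na <- function(truth) {
  ifelse(truth$thickness_px > 0, truth$thickness_px, NA_real_)
}
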