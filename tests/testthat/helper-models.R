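# shared builders for models used across test files

`%||%` <- function(a, b) if (is.null(a)) b else a

two_step <- function() make_irreversible_chain(2, k = c(2, 4), x0 = 1)

# linear oscillator with decaying amplitude: eigenvalues -gamma +/- i
damped_oscillator <- function(gamma = 0.1) {
  kinetic_model(
    species = data.frame(id = c("u", "v"), initial = c(1, 0)),
    parameters = data.frame(id = "gamma", value = gamma),
    rate_rules = list(u = "-gamma*u + v", v = "-u - gamma*v"),
    id = "damped_oscillator")
}

# Hopf normal form: stable limit cycle of radius 1, angular speed omega,
# hence period exactly 2*pi/omega once on the cycle
limit_cycle_oscillator <- function(omega = 1) {
  kinetic_model(
    species = data.frame(id = c("u", "v"), initial = c(1, 0)),
    parameters = data.frame(id = "omega", value = omega),
    rate_rules = list(u = "u - omega*v - u*(u^2 + v^2)",
                      v = "omega*u + v - v*(u^2 + v^2)"),
    id = "limit_cycle")
}

# independent spectral period estimate: dominant FFT frequency of a
# detrended series, refined by quadratic interpolation of log-power
fft_period <- function(times, x) {
  n <- length(x)
  dt <- times[2] - times[1]
  x <- x - mean(x)
  pw <- Mod(stats::fft(x))^2
  half <- 2:floor(n / 2)
  i <- half[which.max(pw[half])]
  li <- log(pw[c(i - 1, i, i + 1)])
  denom <- li[1] - 2 * li[2] + li[3]
  shift <- if (abs(denom) > 0) 0.5 * (li[1] - li[3]) / denom else 0
  freq <- (i - 1 + shift) / (n * dt)
  1 / freq
}

# directory probed for locally provided published-model SBML files;
# checks are skipped when the files are absent
biomodels_dir <- function() {
  d <- getOption("kingsa.biomodels_dir",
                 file.path(system.file("extdata", package = "kingsa"),
                           "biomodels"))
  d
}

biomodels_file <- function(name) {
  file.path(biomodels_dir(), name)
}
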