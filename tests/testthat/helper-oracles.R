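# Independent literal transcriptions of the twelve isotherm equations,
# kept deliberately separate from the package implementation so the two
# can be compared as implementation vs oracle.

oracle_eval <- function(name, p, aw) {
  switch(name,
    GAB = (p["X_m"] * p["C"] * p["K"] * aw) /
      ((1 - p["K"] * aw) * (1 + (p["C"] - 1) * p["K"] * aw)),
    Peleg = p["a_0"] * aw^p["a_1"] + p["a_2"] * aw^p["a_3"],
    Smith = p["a_1"] - p["a_2"] * log(1 - aw),
    Kuhn = p["a_1"] / log(aw) + p["a_2"],
    DLP = {
      x <- log(-log(aw))
      p["a_0"] + p["a_1"] * x + p["a_2"] * x^2 + p["a_3"] * x^3
    },
    ChungPfost = p["a_1"] - p["a_2"] * log(-log(aw)),
    Caurie = exp(p["a_1"] + p["a_2"] * aw),
    IglesiasChirife = p["a_1"] + p["a_2"] * (aw / (1 - aw)),
    WhiteEiring = 1 / (p["a_1"] + p["a_2"] * aw),
    Polynomial = p["a_0"] + p["a_1"] * aw + p["a_2"] * aw^2 +
      p["a_3"] * aw^3,
    Oswin = p["a_1"] * (aw / (1 - aw))^p["a_2"],
    YanniotisBlahovec = aw / (p["a_0"] + p["a_1"] * aw) +
      aw / (p["a_2"] + p["a_3"] * aw))
}

# draw one random parameter set guaranteed valid on aw in (0.01, 0.99)
random_valid_params <- function(name) {
  u <- function(a, b) runif(1, a, b)
  switch(name,
    GAB = c(X_m = u(0.01, 0.5), C = u(0.5, 100), K = u(0.05, 0.95)),
    Peleg = c(a_0 = u(0, 1), a_1 = u(0.05, 10), a_2 = u(0, 1),
              a_3 = u(0.05, 10)),
    WhiteEiring = {
      a1 <- u(1, 20)
      c(a_1 = a1, a_2 = u(-0.9, 0.9) * a1)
    },
    Oswin = c(a_1 = u(0.01, 1), a_2 = u(-2, 2)),
    YanniotisBlahovec = c(a_0 = u(0.5, 5), a_1 = u(-0.45, 5),
                          a_2 = u(0.5, 5), a_3 = u(-0.45, 5)),
    Caurie = c(a_1 = u(-3, 1), a_2 = u(-1, 2)),
    {
      pn <- switch(name,
                   DLP = c("a_0", "a_1", "a_2", "a_3"),
                   Polynomial = c("a_0", "a_1", "a_2", "a_3"),
                   c("a_1", "a_2"))
      setNames(runif(length(pn), -1, 1), pn)
    })
}

# fixed-temperature truth values producing plausible type-II-ish curves
# on aw in (0.1, 0.85); used by the per-model recovery smoke suite
smoke_truth <- function(name) {
  switch(name,
    GAB = c(X_m = 0.102, C = 15, K = 0.75),
    Peleg = c(a_0 = 0.2, a_1 = 0.35, a_2 = 0.25, a_3 = 6),
    Smith = c(a_1 = 0.05, a_2 = 0.12),
    Kuhn = c(a_1 = -0.02, a_2 = 0.05),
    DLP = c(a_0 = 0.12, a_1 = -0.05, a_2 = 0.01, a_3 = -0.005),
    ChungPfost = c(a_1 = 0.1, a_2 = 0.05),
    Caurie = c(a_1 = -2.8, a_2 = 1.5),
    IglesiasChirife = c(a_1 = 0.05, a_2 = 0.02),
    WhiteEiring = c(a_1 = 15, a_2 = -12),
    Polynomial = c(a_0 = 0.05, a_1 = 0.2, a_2 = -0.3, a_3 = 0.35),
    Oswin = c(a_1 = 0.12, a_2 = 0.35),
    YanniotisBlahovec = c(a_0 = 2, a_1 = 3, a_2 = 20, a_3 = -18))
}

# single-temperature wet/desorption records from a fixed-T truth
smoke_dataset <- function(name, params = smoke_truth(name),
                          branch = "desorption") {
  g <- ddi_grid(branch)
  spec <- model_spec(name, temp_mode = "fixed")
  data.frame(aw = g, temperature_c = 25, method = "wet", branch = branch,
             replicate = 1,
             xe = evaluate_model(spec, params, g),
             stringsAsFactors = FALSE)
}
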