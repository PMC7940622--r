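# Shared fixtures: the default model is expensive enough to build once.
the_model <- build_default_model()

# Independent polyline/forward-kinematics oracle using complex arithmetic
# (deliberately different machinery from the package's 2D rotation code).
oracle_muscle_length <- function(model, q, muscle) {
  qq <- c(pitch = 0, hip = 0, knee = 0, ankle = 0, mp = 0)
  qq[names(q)] <- q
  psi <- c(HAT = pi / 2 - qq[["pitch"]])
  psi["thigh"] <- psi[["HAT"]] - pi + qq[["hip"]]
  psi["shank"] <- psi[["thigh"]] + qq[["knee"]]
  psi["foot"]  <- psi[["shank"]] + qq[["ankle"]]
  psi["phalanges"] <- psi[["foot"]] + qq[["mp"]]
  len <- setNames(model$segments$length, model$segments$name)
  org <- c(HAT = 0 + 0i)
  org["thigh"] <- 0 + 0i
  org["shank"] <- org[["thigh"]] + len[["thigh"]] * exp(1i * psi[["thigh"]])
  org["foot"]  <- org[["shank"]] + len[["shank"]] * exp(1i * psi[["shank"]])
  org["phalanges"] <- org[["foot"]] + len[["foot"]] * exp(1i * psi[["foot"]])
  mus <- model$muscles[[which(vapply(model$muscles, `[[`, "", "name") ==
                                muscle)]]
  pts <- sapply(seq_len(nrow(mus$path)), function(i) {
    s <- mus$path$segment[i]
    org[[s]] + complex(real = mus$path$x[i], imaginary = mus$path$y[i]) *
      exp(1i * psi[[s]])
  })
  sum(Mod(diff(pts)))
}

# hand-crafted plausible locomotor pattern (extensors in stance, flexors in
# swing); used where tests need a non-trivial but deterministic genome
crafted_genome <- function() {
  pat <- rbind(
    IL   = c(0.8, 0.35, 4.3, 5.6, 0.3, 0.3),
    GMED = c(0.8, 0.40, 0.5, 3.0, 0.4, 0.4),
    VAS  = c(0.8, 0.30, 0.3, 5.9, 0.3, 0.2),
    TA   = c(0.6, 0.30, 4.5, 0.1, 0.3, 0.1),
    SOL  = c(0.7, 0.50, 2.5, 3.5, 0.6, 0.3),
    RF   = c(0.6, 0.25, 0.3, 4.3, 0.3, 0.3),
    BIFl = c(0.7, 0.30, 5.8, 0.8, 0.2, 0.4),
    GAS  = c(0.8, 0.40, 3.0, 0.5, 0.4, 0.3),
    EDL  = c(0.6, 0.25, 4.6, 0.1, 0.3, 0.2),
    FDL  = c(0.8, 0.30, 3.3, 0.3, 0.3, 0.3))
  patterns_to_genome(pat)
}

reference_genome_path <- function(name = "genome_reference.txt") {
  system.file("extdata", name, package = "macaquegait")
}
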