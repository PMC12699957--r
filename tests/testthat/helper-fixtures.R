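# shared fixtures: random-but-valid poses and raw samples matching summaries

# dense (frame x landmark x axis) view of a sequence
seq_to_arr <- function(seq) exerscore:::seq_to_array(seq)

# random canonical angle vector comfortably inside [0, 180]
random_canonical_angles <- function() {
  a <- stats::runif(9, 20, 160)
  names(a) <- names(neutral_angles())
  a
}

# a seeded short synthetic recording with mild noise
noisy_sequence <- function(movement = "punching", seed = 7, sd = 3,
                           duration = 2, fps = 30) {
  generate_movement(movement, duration = duration, fps = fps,
                    noise = noise_spec(angular_sd = sd, seed = seed))
}

# raw sample of size n with sample mean and sd matching exactly
# (affine rescaling of a normal draw)
raw_matching <- function(n, m, s) {
  x <- stats::rnorm(n)
  m + s * (x - mean(x)) / stats::sd(x)
}

# textbook one-way ANOVA on raw data via stats::lm/anova
raw_anova <- function(samples) {
  y <- unlist(samples)
  g <- factor(rep(seq_along(samples), lengths(samples)))
  tab <- stats::anova(stats::lm(y ~ g))
  list(F = tab$`F value`[1], p = tab$`Pr(>F)`[1],
       eta2 = tab$`Sum Sq`[1] / sum(tab$`Sum Sq`))
}
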