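# Small in-code fixtures shared across tests.

# Minimal 2-item scale, levels 0-2, with one sum group over both items.
tiny_scale <- function() {
  ordinal_scale("tiny", data.frame(
    item_id = c("i1", "i2"), label = c("item 1", "item 2"),
    section = "S", min_level = 0L, max_level = 2L),
    sum_groups = list(TOTAL = c("i1", "i2")))
}

# Long-format ratings for a full paired design: every subject rated by
# both raters on both occasions, scores given per (item) as a function.
tiny_ratings <- function(subjects, raters = c("R1", "R2"), occasions = 1:2,
                         items = c("i1", "i2"), score_fun) {
  grid <- expand.grid(subject_id = subjects, rater_id = raters,
                      occasion = occasions, item_id = items,
                      stringsAsFactors = FALSE)
  grid$score <- mapply(score_fun, grid$subject_id, grid$rater_id,
                       grid$occasion, grid$item_id)
  grid
}

comparison_spec_for_test <- function(mode, rater = NULL, occasions = 1:2,
                                     occasion = NULL) {
  rankagree:::comparison_spec(mode, rater = rater, occasions = occasions,
                              occasion = occasion)
}

# A deterministic FMA-LE dataset with constant scores per assessment.
constant_fma_ratings <- function(n = 4, score = 2L) {
  scale <- load_scale("fma_le")
  cfg <- synthetic_config(n_subjects = n, shift_prob = 0, noise_prob = 0,
                          item_marginals = local({
                            m <- c(0, 0, 0); m[score + 1] <- 1; m
                          }), seed = 1)
  generate_study(cfg)
}
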