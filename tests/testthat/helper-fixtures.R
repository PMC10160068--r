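# Small community configuration for fast end-to-end tests.
small_config <- function(seed = 1L, ...) {
  defaults <- list(
    n_genera = 4L, contigs_per_genus = 3L,
    contig_length_range = c(1500L, 2500L),
    n_viral_contigs = 10L, viral_length_range = c(1500L, 2000L),
    n_samples_per_condition = 3L, reads_per_sample = 5000L,
    seed = seed)
  do.call(synthetic_config, utils::modifyList(defaults, list(...)))
}

# Planted array helper: repeat/spacer chain with random flanks. Spacer
# first/last characters alternate so the chain is not one-base extensible.
planted_array_contig <- function(repeat_len = 28, spacer_len = 32, n_spacers = 2,
                                 flank = 400) {
  rep_seq <- rand_seq(repeat_len)
  starts <- c("A", "C", "G", "T")
  spacers <- vapply(seq_len(n_spacers), function(i) {
    core <- rand_seq(spacer_len - 2)
    paste0(starts[(i - 1) %% 4 + 1], core, starts[i %% 4 + 1])
  }, character(1))
  body <- paste0(rep_seq, paste(vapply(spacers, function(s) paste0(s, rep_seq),
                                       character(1)), collapse = ""))
  left <- rand_seq(flank)
  right <- rand_seq(flank)
  list(sequence = paste0(left, body, right),
       repeat_seq = rep_seq, spacers = spacers,
       start = flank, end = flank + nchar(body))
}
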