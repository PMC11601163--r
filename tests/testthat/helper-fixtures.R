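# Fixture builders shared across test files. Everything is generated in
# code under a fixed seed; no binary fixtures on disk.

demo_channels <- c("Ir191", "Ir193", "Pd104", "Pd105", "Pd106",
                   "panAkt", "totalERK", "m1", "m2", "m3")

# raw-count table: lognormal-ish positive intensities, two samples
make_raw_table <- function(n = 40, seed = 1, channels = demo_channels,
                           n_samples = 2) {
  set.seed(seed)
  values <- matrix(rlnorm(n * length(channels), meanlog = 3, sdlog = 0.6),
                   n, length(channels), dimnames = list(NULL, channels))
  event_table(values,
              sample_labels = rep(paste0("s", seq_len(n_samples)),
                                  length.out = n))
}

demo_panel <- function(markers = c("m1", "m2", "m3")) {
  panel_config(dna_channels = c("Ir191", "Ir193"),
               barcode_channels = c("Pd104", "Pd105", "Pd106"),
               n_top_barcodes = 2,
               antibody_suc_markers = c("panAkt", "totalERK"),
               markers_to_correct = markers)
}

# table with a known linear dependence on a latent factor, for model tests
make_confounded_table <- function(n_per_sample = 200, n_samples = 3,
                                  seed = 2) {
  set.seed(seed)
  n <- n_per_sample * n_samples
  samples <- rep(paste0("line", seq_len(n_samples)), each = n_per_sample)
  latent <- rnorm(n)
  raw <- function(mu, slope) pmax(0, exp(mu + slope * latent +
                                         rnorm(n, sd = 0.2)))
  values <- cbind(Ir191 = raw(4.0, 0.8), Ir193 = raw(4.1, 0.8),
                  Pd104 = raw(3.0, 0.7), Pd105 = raw(3.2, 0.7),
                  Pd106 = raw(2.9, 0.7),
                  panAkt = raw(4.5, 0.9), totalERK = raw(4.4, 0.9),
                  m1 = raw(3.5, 1.0), m2 = raw(4.0, 0.5),
                  m3 = raw(3.0, 0.0))
  event_table(values, sample_labels = samples)
}

write_demo_panel_json <- function(path) {
  jsonlite::write_json(list(
    dna_channels = c("Ir191", "Ir193"),
    barcode_channels = c("Pd104", "Pd105", "Pd106"),
    n_top_barcodes = 2,
    antibody_suc_markers = c("panAkt", "totalERK"),
    markers_to_correct = c("m1", "m2", "m3")), path)
  path
}
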