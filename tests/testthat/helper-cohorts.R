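# Fixture builders shared across test files. All cohorts are generated in
# code at test time; no data files are stored.

# Minimal 3-category taxonomy used by the io/hierarchy unit tests.
demo_taxonomy <- function() {
  taxonomy(list(blood = c("AML", "CLL"), psych = c("BD", "SZ")),
           terminal = "HEALTHY")
}

# Small well-separated hierarchical cohort: strong category markers,
# weaker disease markers, one class of each size profile.
demo_cohort <- function(seed = 11L, n_proteins = 30L,
                        n = c(AML = 20, CLL = 20, BD = 20, SZ = 60,
                              HEALTHY = 40),
                        cat_shift = 3, dis_shift = 2, noise_sd = 1) {
  tax <- demo_taxonomy()
  keep <- function(mk) {
    mk <- lapply(mk, function(m) m[m$protein <= n_proteins, , drop = FALSE])
    mk[vapply(mk, nrow, integer(1)) > 0L]
  }
  cfg <- sim_config(
    n, tax, n_proteins = n_proteins,
    category_markers = keep(list(
      blood = data.frame(protein = 1:3, shift = cat_shift),
      psych = data.frame(protein = 4:6, shift = cat_shift))),
    disease_markers = keep(list(
      AML = data.frame(protein = 7, shift = dis_shift),
      CLL = data.frame(protein = 8, shift = dis_shift),
      BD = data.frame(protein = 9, shift = dis_shift),
      SZ = data.frame(protein = 10, shift = dis_shift),
      HEALTHY = data.frame(protein = 11, shift = dis_shift))),
    noise_sd = noise_sd, seed = seed)
  simulate_cohort(cfg)
}

# Imbalanced 24-phenotype cohort emulating the multi-disease study layout:
# 4 categories (4 + 2 + 5 + 12 diseases) plus a terminal healthy class,
# strong category-level markers and weaker disease-level markers. Class
# sizes are the study's per-disease counts scaled down ~10x.
study_taxonomy <- function() {
  taxonomy(list(
    blood = c("AML", "CLL", "LYMPH", "MYEL"),
    psychiatric = c("BD", "SZ"),
    metabolic = c("ARLD", "CLD", "HCC", "MASLD", "VIRAL"),
    tumor = c("BRC", "CRC", "CVX", "ENDC", "GLIOM", "LUNGC", "MENI",
              "OVC", "PCa", "PIT-NET", "PRC", "SI-NET")),
    terminal = "HEALTHY")
}

study_scale_config <- function(seed, n_proteins = 200L,
                               cat_shift = 3, dis_shift = 1.5,
                               noise_sd = 1) {
  tax <- study_taxonomy()
  n <- c(AML = 5, CLL = 5, LYMPH = 6, MYEL = 5, BD = 5, SZ = 10,
         ARLD = 5, CLD = 5, HCC = 8, MASLD = 12, VIRAL = 7,
         BRC = 16, CRC = 31, CVX = 11, ENDC = 11, GLIOM = 16, LUNGC = 29,
         MENI = 5, OVC = 18, PCa = 7, `PIT-NET` = 5, PRC = 17, `SI-NET` = 5,
         HEALTHY = 14)
  cats <- lapply(seq_along(tax$categories), function(j) {
    data.frame(protein = (j - 1L) * 3L + 1:3, shift = cat_shift)
  })
  names(cats) <- names(tax$categories)
  labels <- setdiff(names(n), "HEALTHY")
  dis <- lapply(seq_along(labels), function(i) {
    data.frame(protein = 12L + i, shift = dis_shift)
  })
  names(dis) <- labels
  dis$HEALTHY <- data.frame(protein = 12L + length(labels) + 1L,
                            shift = dis_shift)
  sim_config(n, tax, n_proteins = n_proteins, category_markers = cats,
             disease_markers = dis, noise_sd = noise_sd, seed = seed)
}

# Fast node specs for the 24-class fixtures (fewer trees / epochs than the
# defaults; the tests exercise contracts, not asymptotics).
fast_specs <- function() {
  list(first_stage = node_spec("perceptron", epochs = 15L),
       second_stage = list(
         blood = node_spec("extratrees", num.trees = 60L),
         psychiatric = node_spec("sgd", epochs = 10L),
         metabolic = node_spec("ridge"),
         tumor = node_spec("logistic", maxit = 60L)))
}

fit_fast <- function(train, tax = study_taxonomy(), seed = 1L,
                     oversample = TRUE) {
  sp <- fast_specs()
  two_stage(train, tax, first_stage = sp$first_stage,
            second_stage = sp$second_stage, oversample = oversample,
            seed = seed)
}

# Flat multiclass logistic baseline fitted on a cohort; returns a label
# predictor closure.
flat_logistic <- function(train, seed = 1L, maxit = 100L) {
  fit <- fit_node(node_spec("logistic", maxit = maxit), train$npx,
                  train$labels, seed = seed)
  function(X) {
    pr <- node_probs(fit, X)
    fit$levels[max.col(pr, ties.method = "first")]
  }
}

# Well-separated cohort with a 137-sample healthy class (so the 70% split
# puts 96 healthy samples in training) and small disease classes.
sens_cohort <- function(seed = 51) {
  tax <- demo_taxonomy()
  cfg <- sim_config(
    c(AML = 12, CLL = 12, BD = 12, SZ = 20, HEALTHY = 137), tax,
    n_proteins = 15,
    category_markers = list(
      blood = data.frame(protein = 1:2, shift = 4),
      psych = data.frame(protein = 3:4, shift = 4)),
    disease_markers = list(
      AML = data.frame(protein = 5, shift = 3),
      CLL = data.frame(protein = 6, shift = 3),
      BD = data.frame(protein = 7, shift = 3),
      SZ = data.frame(protein = 8, shift = 3)),
    noise_sd = 1, seed = seed)
  simulate_cohort(cfg)
}
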