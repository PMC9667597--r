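# Independent oracles used by unit and acceptance tests. These deliberately
# use naive set arithmetic / explicit loops so they share no code path with
# the package implementations they check.

# Jaccard via explicit index sets
jaccard_set_oracle <- function(a, b) {
  A <- which(a == 1)
  B <- which(b == 1)
  u <- length(union(A, B))
  if (u == 0) 0 else length(intersect(A, B)) / u
}

# supervised contrastive loss via the literal triple loop over (i, j, k)
scl_loop_oracle <- function(z, y, tau) {
  n <- nrow(z)
  cossim <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  total <- 0
  for (i in seq_len(n)) {
    pos <- setdiff(which(y == y[i]), i)
    if (length(pos) == 0) next
    li <- 0
    for (j in pos) {
      denom <- 0
      for (k in setdiff(seq_len(n), i)) {
        denom <- denom + exp(cossim(z[i, ], z[k, ]) / tau)
      }
      li <- li + log(exp(cossim(z[i, ], z[j, ]) / tau) / denom)
    }
    total <- total + (-1 / length(pos)) * li
  }
  total / n
}

# a small deterministic descriptor set used across tests
tiny_descriptor_set <- function() {
  descriptor_set(
    c("d1", "d2", "d3"),
    list(substructure = rbind(c(1, 1, 1, 0, 0),
                              c(0, 1, 1, 1, 0),
                              c(0, 0, 0, 0, 1)),
         target = rbind(c(1, 0, 0),
                        c(1, 0, 0),
                        c(0, 1, 1))))
}

# nearest-archetype classification from raw descriptor bits + the planted
# archetype-pair -> class map; the recoverability oracle for the generator
planted_label_oracle <- function(syn) {
  gt <- syn$ground_truth
  bits <- do.call(cbind, syn$descriptors$blocks)
  tmpl <- do.call(cbind, gt$templates)
  arch_of <- apply(bits, 1, function(b) {
    which.min(colSums(abs(t(tmpl) - b)))
  })
  names(arch_of) <- syn$descriptors$drug_ids
  cc <- gt$combo_classes
  key <- paste(cc$arch_a, cc$arch_b)
  cls <- setNames(cc$class, key)
  recs <- syn$ddis$records
  a <- pmin(arch_of[recs$drugA], arch_of[recs$drugB])
  b <- pmax(arch_of[recs$drugA], arch_of[recs$drugB])
  unname(cls[paste(a, b)])
}

# small trained model on a tiny synthetic problem, cached per test run
tiny_trained_model <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    syn <- generate_synthetic(synth_config(n_drugs = 24, n_classes = 3,
                                           descriptors_per_type = 32,
                                           pair_coverage = 0.6, seed = 11))
    prof <- build_similarity_profiles(syn$descriptors)
    nc <- network_config(ncol(prof$matrix), 3, n_tokens = 4, h1 = 32,
                         h2 = 16, dropout_rate = 0.1, seed = 11)
    tc <- train_config(learning_rate = 1e-2, batch_size = 32, epochs = 15,
                       switch_epoch = 5, seed = 11)
    m <- ddi_train(prof, syn$ddis$records, tc, nc, n_classes = 3)
    cache <<- list(syn = syn, prof = prof, model = m, netcfg = nc,
                   traincfg = tc)
    cache
  }
})
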