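# shared fixtures: everything is generated in code, no stored data

random_mask <- function(h, w, p = 0.4) {
  matrix(rbinom(h * w, 1, p), h, w)
}

random_prob <- function(h, w) matrix(runif(h * w), h, w)

random_image <- function(side) array(runif(side * side * 3), c(side, side, 3))

# brute-force pairwise-concordance AUC oracle
auc_oracle <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  tot / (length(pos) * length(neg))
}

# a tiny network whose output is (nearly) constant: sigmoid(bias)
constant_net <- function(side, value = 1) {
  net <- build_msmku(msmku_config(side, 2L, seed = 1L))
  net$layers$head$W[] <- 0
  net$layers$head$b[] <- if (value >= 0.5) 10 else -10
  net
}

# training pairs for a quick disc-segmentation task
od_pairs <- function(n, side, seed, rare_fraction = 0) {
  ds <- generate_dataset(n, rare_fraction = rare_fraction, side = side,
                         seed = seed)
  lapply(ds$items, function(it) list(image = it$image, mask = it$od_mask))
}
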