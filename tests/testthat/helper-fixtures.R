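# shared fixtures, built in code

toy_counts <- function(n_otus = 5, n_samples = 4, lambda = 20, seed = 1) {
  set.seed(seed)
  m <- matrix(rpois(n_otus * n_samples, lambda), n_otus)
  m[m == 0] <- 1
  rownames(m) <- paste0("OTU", seq_len(n_otus))
  colnames(m) <- paste0("S", seq_len(n_samples))
  count_table(m)
}

seed_meta <- function(ages = c(48, 62, 76, 90, 106, 120, 141),
                      n_bio = 3, year = 2018) {
  n <- length(ages) * n_bio
  sample_meta(data.frame(
    sample_id = paste0("s", seq_len(n)), compartment = "Se",
    age_days = rep(ages, each = n_bio), year = year, site = "SW",
    bio_rep = rep(seq_len(n_bio), length(ages)), tech_rep = 1))
}

# a small assoc_network built directly from an edge list
toy_network <- function(edges, nodes = NULL, context = list(
                          compartment = "Se", age = "all")) {
  ed <- data.frame(otu_a = edges[, 1], otu_b = edges[, 2],
                   rho = if (ncol(edges) > 2) as.numeric(edges[, 3]) else 0.5,
                   q = 0.01, stringsAsFactors = FALSE)
  ed$sign <- ifelse(ed$rho > 0, "pos", "neg")
  if (is.null(nodes)) nodes <- sort(unique(c(ed$otu_a, ed$otu_b)))
  structure(list(edges = ed,
                 nodes = data.frame(otu_id = nodes,
                                    stringsAsFactors = FALSE),
                 context = context),
            class = "assoc_network")
}

# brute-force hypergeometric upper tail by direct summation of the mass
hyper_tail_bruteforce <- function(k, n_successes, n_other, n_draws) {
  xs <- k:min(n_draws, n_successes)
  if (k > min(n_draws, n_successes)) return(0)
  sum(choose(n_successes, xs) * choose(n_other, n_draws - xs)) /
    choose(n_successes + n_other, n_draws)
}
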