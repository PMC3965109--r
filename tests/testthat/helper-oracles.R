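# Exact-arithmetic oracle for the hypergeometric upper tail, independent of
# the package's log-space implementation. Binomial coefficients come from a
# Pascal-triangle table built by integer additions; for N <= 40 every
# coefficient and every partial numerator sum is below 2^53, so all integer
# arithmetic in doubles is exact and the single final division is correct to
# 0.5 ulp.
pascal_table <- local({
  tab <- NULL
  function(N) {
    if (is.null(tab) || nrow(tab) < N + 1L) {
      t2 <- matrix(0, N + 1L, N + 1L)
      t2[, 1L] <- 1
      for (n in 1:N) for (k in 1:n) {
        t2[n + 1L, k + 1L] <- t2[n, k] + t2[n, k + 1L]
      }
      tab <<- t2
    }
    tab
  }
})

exact_hyper_tail <- function(N, n1, n2, k) {
  ch <- pascal_table(max(N, 40L))
  i <- k:min(n1, n2)
  num <- sum(ch[n1 + 1L, i + 1L] * ch[N - n1 + 1L, n2 - i + 1L])
  num / ch[N + 1L, n2 + 1L]
}

# upper tail of all overlap counts at once (cumulative from the top),
# for sweeping every admissible k of one (N, n1, n2) triple
exact_hyper_tail_all_k <- function(N, n1, n2) {
  ch <- pascal_table(max(N, 40L))
  i <- 0:min(n1, n2)
  terms <- ch[n1 + 1L, i + 1L] * ch[N - n1 + 1L, n2 - i + 1L]
  rev(cumsum(rev(terms))) / ch[N + 1L, n2 + 1L]
}

# three-pair toy ortholog table: w1/w2/h1/h2 collapse to one group,
# w3-h3 stays separate
toy_pairs <- function() {
  data.frame(worm_gene = c("w1", "w1", "w2", "w3"),
             human_gene = c("h1", "h2", "h2", "h3"),
             bootstrap = 100, stringsAsFactors = FALSE)
}

# n one-to-one pairs wg1-hg1 ... wgn-hgn
one_to_one_pairs <- function(n, bootstrap = 100) {
  data.frame(worm_gene = paste0("wg", seq_len(n)),
             human_gene = paste0("hg", seq_len(n)),
             bootstrap = bootstrap, stringsAsFactors = FALSE)
}

make_catalog <- function(terms, genes, source = "OMIM", labels = terms,
                         p_value = NULL) {
  df <- data.frame(term_id = terms, label = labels, gene = genes,
                   stringsAsFactors = FALSE)
  if (!is.null(p_value)) df$p_value <- p_value
  geneset_catalog(df, source)
}

write_tsv <- function(df, path = tempfile(fileext = ".tsv")) {
  writeLines(c(paste(names(df), collapse = "\t"),
               do.call(paste, c(lapply(df, as.character), sep = "\t"))),
             path)
  path
}
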