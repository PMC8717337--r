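# Shared fixtures, built in code.

toy5_text <- "((A:1,B:1):1,(C:1,(D:0.5,E:0.5):0.5):1);"

toy5 <- function() read_newick(text = toy5_text)[[1L]]

# star tree: every tip attached to the root with branch length t
star_tree <- function(n, t = 1) {
  txt <- paste0("(", paste0("s", seq_len(n), ":", t, collapse = ","), ");")
  ape::read.tree(text = txt)
}

# random non-ultrametric tree with branch lengths in (0, 1]
random_tree <- function(n) {
  tr <- ape::rtree(n)
  tr$edge.length <- tr$edge.length + 1e-3  # keep strictly positive
  tr
}

# random binary community over a tree's tips
random_community <- function(tree, n_sites, fill = 0.5) {
  tips <- tree$tip.label
  m <- matrix(rbinom(n_sites * length(tips), 1, fill), n_sites,
              dimnames = list(sprintf("site%02d", seq_len(n_sites)), tips))
  storage.mode(m) <- "double"
  m
}
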