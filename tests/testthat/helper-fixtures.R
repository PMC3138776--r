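# shared toy trees and oracles, built in code at test time

tree3 <- function() read_phylogeny(text = "((A:1,B:1):1,C:2);")
star3 <- function() read_phylogeny(text = "(A:1,B:1,C:1);")
caterpillar5 <- function() read_phylogeny(text = "((((A:1,B:1):1,C:2):1,D:3):1,E:4);")

# 10-tip tree with a 4-tip clade {A,B,C,D} for the enrichment oracle case
tree10 <- function() read_phylogeny(
  text = "(((A:1,B:1):1,(C:1,D:1):1):1,(E:2,(F:1,(G:1,(H:1,(I:1,J:1):1):1):1):1):1);")

toy_records <- function() data.frame(
  taxon = c("T1", "T2", "T1"),
  region = c("Neotropics", "Neotropics", "Neotropics"),
  category = c("Skin", "Skin", "Pain"),
  condition = NA_character_, source = NA_character_,
  stringsAsFactors = FALSE)

write_records_file <- function(records, path = tempfile(fileext = ".tsv")) {
  utils::write.table(records, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# independent patristic oracle: explicit path enumeration via parent pointers
naive_patristic <- function(tree) {
  nt <- ape::Ntip(tree)
  nn <- nt + tree$Nnode
  parent <- rep(NA_integer_, nn)
  plen <- rep(NA_real_, nn)
  for (i in seq_len(nrow(tree$edge))) {
    parent[tree$edge[i, 2]] <- tree$edge[i, 1]
    plen[tree$edge[i, 2]] <- tree$edge.length[i]
  }
  path_up <- function(i) {
    nodes <- i; dist <- 0
    while (!is.na(parent[i])) {
      dist <- c(dist, dist[length(dist)] + plen[i])
      i <- parent[i]
      nodes <- c(nodes, i)
    }
    stats::setNames(dist, nodes)
  }
  paths <- lapply(seq_len(nt), path_up)
  d <- matrix(0, nt, nt, dimnames = list(tree$tip.label, tree$tip.label))
  for (i in seq_len(nt - 1)) for (j in (i + 1):nt) {
    common <- intersect(names(paths[[i]]), names(paths[[j]]))
    d[i, j] <- d[j, i] <- min(paths[[i]][common] + paths[[j]][common])
  }
  d
}

# add-one permutation p from a seeded null vector
perm_p <- function(obs, nulls) (sum(nulls <= obs) + 1) / (length(nulls) + 1)
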