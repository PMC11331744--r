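#' Manual peptide fragmentation schemes
#'
#' Reference cut sets used to benchmark the automatic optimiser against the
#' three manual protein fragmentations: "naive" severs amide C-N bonds,
#' "semi-naive" severs Calpha-N bonds and "non-naive" severs Calpha-C bonds.
#' The backbone is recognised from the graph alone via the repeating
#' N-Calpha-C(=O) motif (no residue metadata needed), and cuts are chosen
#' greedily along the chain: walking from the N-terminus, a bond of the
#' scheme's class is cut as soon as the accumulated fragment reaches the
#' target size.
#'
#' @param graph A `mol_graph` (or atoms tibble) of a single-chain peptide.
#' @param scheme "naive", "semi-naive" or "non-naive".
#' @param n_t Target fragment size in atoms (default 50).
#' @return Tibble of cut bonds (`from`, `to`) ordered along the chain.
#' @export
manual_scheme_cuts <- function(graph, scheme = c("naive", "semi-naive", "non-naive"),
                               n_t = 50) {
  scheme <- match.arg(scheme)
  if (!inherits(graph, "mol_graph")) graph <- mol_graph(graph)
  bb <- .backbone_motifs(graph)
  if (!nrow(bb)) stop("no N-Calpha-C(=O) backbone motif found", call. = FALSE)
  cand <- switch(scheme,
    "naive" = tibble::tibble(from = utils::head(bb$c_prime, -1),
                             to = bb$n[-1]),
    "semi-naive" = tibble::tibble(from = bb$n, to = bb$c_alpha),
    "non-naive" = tibble::tibble(from = bb$c_alpha, to = bb$c_prime)
  )
  # residue position of each candidate bond, for the greedy walk
  cand$residue <- if (scheme == "naive") seq_len(nrow(cand)) else seq_len(nrow(cand))
  if (!nrow(cand)) stop("no bonds of the ", scheme, " class found", call. = FALSE)

  cuts <- list()
  last_cut_atoms <- 0L
  for (k in seq_len(nrow(cand))) {
    # fragment size if we cut here: atoms on the N-terminal side of the bond
    side <- .side_size(graph, cand$from[k], cand$to[k])
    if (side - last_cut_atoms >= n_t) {
      cuts[[length(cuts) + 1L]] <- cand[k, c("from", "to")]
      last_cut_atoms <- side
    }
  }
  out <- if (length(cuts)) dplyr::bind_rows(cuts) else
    tibble::tibble(from = integer(), to = integer())
  out$from2 <- pmin(out$from, out$to); out$to2 <- pmax(out$from, out$to)
  tibble::tibble(from = out$from2, to = out$to2)
}

# atoms on the `from` side of bond from-to (assumes a bridge)
.side_size <- function(graph, from, to) {
  eid <- igraph::get_edge_ids(graph$graph, c(from, to))
  memb <- igraph::components(igraph::delete_edges(graph$graph, eid))$membership
  sum(memb == memb[from])
}

# one row per residue: n, c_alpha, c_prime (carbonyl carbon), ordered
# from the N-terminus
.backbone_motifs <- function(graph) {
  at <- graph$atoms; bonds <- graph$bonds
  nb <- .neighbour_list(nrow(at), bonds)
  has_carbonyl_o <- function(c) {
    any(vapply(nb[[c]], function(o) {
      at$element[o] == "O" &&
        any(bonds$order[(bonds$from == min(c, o) & bonds$to == max(c, o))] == 2L)
    }, TRUE))
  }
  rows <- list()
  for (n_at in which(at$element == "N")) {
    for (ca in nb[[n_at]]) {
      if (at$element[ca] != "C") next
      for (cp in setdiff(nb[[ca]], n_at)) {
        if (at$element[cp] != "C" || !has_carbonyl_o(cp)) next
        rows[[length(rows) + 1L]] <- tibble::tibble(
          n = n_at, c_alpha = ca, c_prime = cp)
      }
    }
  }
  if (!length(rows)) return(tibble::tibble(n = integer(), c_alpha = integer(),
                                           c_prime = integer()))
  bb <- dplyr::distinct(dplyr::bind_rows(rows))
  # order residues by following amide links from the N-terminus
  nterm <- bb$n[!bb$n %in% unlist(lapply(bb$c_prime, function(cp) {
    amide_n <- intersect(nb[[cp]], bb$n)
    amide_n
  }))]
  if (length(nterm)) {
    ordered <- integer()
    cur <- nterm[1]
    repeat {
      r <- which(bb$n == cur)
      if (!length(r)) break
      ordered <- c(ordered, r[1])
      nxt <- intersect(nb[[bb$c_prime[r[1]]]], bb$n)
      nxt <- setdiff(nxt, bb$n[ordered])
      if (!length(nxt)) break
      cur <- nxt[1]
    }
    if (length(ordered) == nrow(bb)) bb <- bb[ordered, ]
  }
  bb
}
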