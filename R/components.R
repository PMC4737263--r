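# Connected-component labelling of a binary 3D array on the 26- (default) or
# 6-connected voxel graph, via igraph on the foreground voxels only.
label_components <- function(mask, connectivity = 26) {
  dm <- dim(mask)
  fg <- which(as.vector(mask) > 0)
  labels <- integer(prod(dm))
  if (length(fg) == 0L) return(array(labels, dm))
  id <- integer(prod(dm))
  id[fg] <- seq_along(fg)
  coords <- arrayInd(fg, dm)
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  keep <- rowSums(abs(offs)) > 0
  if (connectivity == 6) keep <- keep & rowSums(abs(offs)) == 1
  # half neighbourhood: each undirected edge generated once
  offs <- offs[keep, , drop = FALSE]
  offs <- offs[offs[, 3] > 0 | (offs[, 3] == 0 & offs[, 2] > 0) |
                 (offs[, 3] == 0 & offs[, 2] == 0 & offs[, 1] > 0), ,
               drop = FALSE]
  edges <- vector("list", nrow(offs))
  for (r in seq_len(nrow(offs))) {
    nb <- sweep(coords, 2, offs[r, ], `+`)
    ok <- nb[, 1] >= 1 & nb[, 1] <= dm[1] &
      nb[, 2] >= 1 & nb[, 2] <= dm[2] &
      nb[, 3] >= 1 & nb[, 3] <= dm[3]
    if (!any(ok)) next
    lin <- nb[ok, 1] + (nb[ok, 2] - 1L) * dm[1] +
      (nb[ok, 3] - 1L) * dm[1] * dm[2]
    hit <- id[lin] > 0L
    if (!any(hit)) next
    edges[[r]] <- cbind(id[fg[ok]][hit], id[lin][hit])
  }
  em <- do.call(rbind, edges)
  g <- igraph::make_empty_graph(n = length(fg), directed = FALSE)
  if (!is.null(em) && nrow(em) > 0)
    g <- igraph::add_edges(g, t(em))
  membership <- igraph::components(g)$membership
  labels[fg] <- as.integer(membership)
  array(labels, dm)
}

# retain only the largest connected component of a binary vector/array
largest_component <- function(mask, dim = base::dim(mask), connectivity = 26) {
  lab <- label_components(array(mask, dim), connectivity)
  if (max(lab) <= 1L) return(array(as.integer(mask > 0), dim))
  tab <- tabulate(lab[lab > 0])
  array(as.integer(lab == which.max(tab)), dim)
}
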