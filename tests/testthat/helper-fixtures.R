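# Fixture builders and independent oracles, generated in code.

# minimal atom table row
atom_row <- function(element, name, resn, resi, chain, x, y, z) {
  data.frame(element = element, atom_name = name, residue_name = resn,
             residue_index = resi, chain_id = chain, x = x, y = y, z = z)
}

# frame with bare carbon pseudo-atoms at given coordinates
carbon_frame <- function(xyz, box = c(50, 50, 50), chain = NULL,
                         radius = NULL) {
  xyz <- matrix(xyz, ncol = 3)
  n <- nrow(xyz)
  if (is.null(chain)) chain <- rep("A", n)
  at <- data.frame(element = "C", atom_name = "CA", residue_name = "GLY",
                   residue_index = seq_len(n), chain_id = chain,
                   x = xyz[, 1], y = xyz[, 2], z = xyz[, 3])
  if (!is.null(radius)) at$radius <- radius
  molecular_frame(at, box)
}

# two His residues on separate chains along the x axis:
# chain A: CA at origin, ND1 at +3.2 x; chain B: CA at +d_caca x,
# NE2 placed so the closest N-N separation equals d_nn.
his_pair_frame <- function(d_nn, d_caca, box = c(50, 50, 50), shift = 20) {
  at <- rbind(
    atom_row("C", "CA",  "HIS", 1L, "A", 0, 0, 0),
    atom_row("N", "ND1", "HIS", 1L, "A", 3.2, 0, 0),
    atom_row("C", "CA",  "HIS", 1L, "B", d_caca, 0, 0),
    atom_row("N", "NE2", "HIS", 1L, "B", 3.2 + d_nn, 0, 0))
  at$x <- at$x + shift; at$y <- at$y + shift; at$z <- at$z + shift
  molecular_frame(at, box)
}

# Monte-Carlo surface-rejection SASA oracle: sample points uniformly on each
# probe-expanded sphere and keep those outside every other expanded sphere.
# Independent of the Shrake-Rupley implementation path.
mc_sasa_oracle <- function(xyz, radii, probe = 1.4, n_per_atom = 4e5,
                           seed = 424242) {
  set.seed(seed)
  xyz <- matrix(xyz, ncol = 3)
  re <- radii + probe
  total <- 0
  for (i in seq_len(nrow(xyz))) {
    u <- matrix(rnorm(3 * n_per_atom), ncol = 3)
    u <- u / sqrt(rowSums(u^2))
    p <- sweep(u * re[i], 2, xyz[i, ], "+")
    ok <- rep(TRUE, n_per_atom)
    for (j in seq_len(nrow(xyz))[-i]) {
      d2 <- rowSums(sweep(p, 2, xyz[j, ])^2)
      ok <- ok & d2 > re[j]^2
    }
    total <- total + mean(ok) * 4 * pi * re[i]^2
  }
  total
}

# brute-force O(n^2) minimum-image distance tally (histogram oracle)
brute_pair_histogram <- function(xyz, box, edges) {
  n <- nrow(xyz)
  counts <- numeric(length(edges) - 1L)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      d <- xyz[j, ] - xyz[i, ]
      d <- d - box * round(d / box)
      r <- sqrt(sum(d^2))
      if (r <= edges[length(edges)]) {
        b <- findInterval(r, edges, rightmost.closed = TRUE)
        counts[b] <- counts[b] + 1
      }
    }
  }
  counts
}

# brute-force connected components of the chain-contact graph
brute_chain_components <- function(frame, cutoff) {
  at <- frame$atoms
  pep <- which(!(at$residue_name %in% c("HOH", "SOL", "WAT", "TIP3")) &
                 at$element != "H")
  chains <- sort(unique(at$chain_id[pep]))
  nc <- length(chains)
  adj <- matrix(FALSE, nc, nc)
  x <- as.matrix(at[pep, c("x", "y", "z")])
  cid <- match(at$chain_id[pep], chains)
  for (i in seq_len(length(pep) - 1L)) {
    for (j in (i + 1L):length(pep)) {
      if (cid[i] == cid[j]) next
      d <- x[j, ] - x[i, ]
      d <- d - frame$box * round(d / frame$box)
      if (sqrt(sum(d^2)) <= cutoff) adj[cid[i], cid[j]] <- adj[cid[j], cid[i]] <- TRUE
    }
  }
  comp <- rep(NA_integer_, nc)
  cur <- 0L
  for (s in seq_len(nc)) {
    if (!is.na(comp[s])) next
    cur <- cur + 1L
    stack <- s
    while (length(stack)) {
      v <- stack[1]; stack <- stack[-1]
      if (!is.na(comp[v])) next
      comp[v] <- cur
      stack <- c(stack, which(adj[v, ] & is.na(comp)))
    }
  }
  split(chains, comp)
}
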