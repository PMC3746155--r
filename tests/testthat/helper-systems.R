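# fixtures are built in code: small systems with hand-placed particles

tiny_scheme <- function() {
  segmentScheme(resname = rep("LIP", 4),
                particle = c("NC3", "PO4", "GL1", "C1A"),
                segment = c("head_terminal", "phosphate", "glycerol",
                            "tail"))
}

# one particle row; lipids get resname LIP, proteins a standard AA
p_row <- function(x, y, z, name = "BB", resname = "GLY", resseq = 1L,
                  chain = "A") {
  data.frame(name = name, resname = resname, resseq = as.integer(resseq),
             inscode = "", chain = chain, molecule_id = NA_integer_,
             element = "", x = x, y = y, z = z, stringsAsFactors = FALSE)
}

sys_from_rows <- function(..., box = numeric(0),
                          resolution = "coarse_grained") {
  df <- do.call(rbind, list(...))
  df$molecule_id <- lipidprint:::assignMoleculeIds(df)
  new("MolecularSystem", particles = df, box = box,
      resolution = resolution)
}

annot_from_rows <- function(..., box = numeric(0),
                            resolution = "coarse_grained",
                            scheme = tiny_scheme()) {
  # fixtures often use partial lipids (a lone tail bead), so the
  # unresolved-phosphate guard is off here
  classifyParticles(sys_from_rows(..., box = box,
                                  resolution = resolution), scheme,
                    requirePhosphate = FALSE)
}

# stack identically shaped systems into a trajectory
traj_from_systems <- function(systems) {
  s1 <- systems[[1]]
  p <- particles(s1)
  arr <- array(NA_real_, c(nrow(p), 3L, length(systems)))
  for (f in seq_along(systems)) arr[, , f] <- coords(systems[[f]])
  new("Trajectory", topology = p[, setdiff(names(p), c("x", "y", "z"))],
      coords = arr, box = s1@box, resolution = s1@resolution)
}

# a lipid whose four beads sit on a z stack above/below the phosphate
lip_rows <- function(x, y, zphos, resseq, sgn = 1, chain = "L") {
  rbind(p_row(x, y, zphos + 2 * sgn, "NC3", "LIP", resseq, chain),
        p_row(x, y, zphos, "PO4", "LIP", resseq, chain),
        p_row(x, y, zphos - 2.5 * sgn, "GL1", "LIP", resseq, chain),
        p_row(x, y, zphos - 7 * sgn, "C1A", "LIP", resseq, chain))
}

# contact profile built directly from per-residue segment fractions
mk_profile <- function(resnames, seg_matrix = NULL, head = NULL,
                       tail = NULL, chain = "A", tag = "p",
                       scale = "fraction", nframes = 10L) {
  n <- length(resnames)
  if (is.null(seg_matrix)) {
    seg_matrix <- cbind(head_terminal = rep(0, n), phosphate = rep(0, n),
                        glycerol = head, tail = tail)
  }
  hg <- pmax(seg_matrix[, 1], seg_matrix[, 2], seg_matrix[, 3])
  residues <- data.frame(chain = chain, resseq = seq_len(n), inscode = "",
                         resname = resnames,
                         head_terminal = seg_matrix[, 1],
                         phosphate = seg_matrix[, 2],
                         glycerol = seg_matrix[, 3],
                         tail = seg_matrix[, 4],
                         headgroup_fraction = if (is.null(head)) hg else head,
                         tail_fraction = if (is.null(tail))
                           seg_matrix[, 4] else tail,
                         stringsAsFactors = FALSE)
  new("ContactProfile", residues = residues, nFrames = as.integer(nframes),
      sourceTag = tag, scale = scale)
}

# protein-only system matching a profile's residues (for occurrence counts)
mk_system_for <- function(profile) {
  r <- profileTable(profile)
  rows <- lapply(seq_len(nrow(r)), function(i)
    p_row(i, 0, 0, "BB", r$resname[i], r$resseq[i], r$chain[i]))
  do.call(sys_from_rows, rows)
}
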