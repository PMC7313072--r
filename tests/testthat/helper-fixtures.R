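## Hand-crafted fixtures built in code. makeTestReference writes a FASTA in
## the gene|class|anchor dialect and loads it through the public API, so
## fixture construction also exercises reference I/O.

makeTestReference <- function(v, j, vAnchor, jAnchor) {
  stopifnot(length(v) == length(vAnchor), length(j) == length(jAnchor))
  path <- tempfile(fileext = ".fasta")
  lines <- character(0)
  for (i in seq_along(v))
    lines <- c(lines, sprintf(">%s|V|%d", names(v)[i], vAnchor[i]), v[i])
  for (i in seq_along(j))
    lines <- c(lines, sprintf(">%s|J|%d", names(j)[i], jAnchor[i]), j[i])
  writeLines(lines, path)
  loadReferenceFasta(path, versionTag = "test")
}

## a tiny fixed reference with 3-nt trimmable flanks around the anchors:
## V = 24 nt prefix + TGT + AAA ; J = AAA + TTT + GGA + 30 nt tail
tinyReference <- function() {
  set.seed(99)
  v1 <- paste0(randomDnaStr(24), "TGT", "AAA")
  v2 <- paste0(randomDnaStr(24), "TGC", "CCA")
  j1 <- paste0("AAA", "TTT", "GGA", randomDnaStr(30))
  j2 <- paste0("CCA", "TTC", "GGC", randomDnaStr(30))
  makeTestReference(v = c(TRAV1 = v1, TRAV2 = v2),
                    j = c(TRAJ18 = j1, TRAJ33 = j2),
                    vAnchor = c(25L, 25L), jAnchor = c(4L, 4L))
}

## ground-truth recovery rate of an annotation against a simulation
recoveryRate <- function(ann, truth) {
  tr <- cloneTable(truth)
  ro <- readOrigin(truth)
  ok <- !is.na(ann$v_call) & !is.na(ann$j_call) & !is.na(ann$junction_aa) &
    ann$v_call == tr$v_name[ro$clone_index] &
    ann$j_call == tr$j_name[ro$clone_index] &
    ann$junction_aa == tr$cdr3_aa[ro$clone_index]
  mean(ok)
}

## observed clonotype-key counts implied by the ground truth (clones that
## received zero reads are absent, duplicated keys aggregate)
truthKeyCounts <- function(truth) {
  tr <- cloneTable(truth)
  ro <- readOrigin(truth)
  key <- paste(tr$v_name[ro$clone_index], tr$j_name[ro$clone_index],
               tr$cdr3_aa[ro$clone_index], sep = "|")
  table(key)
}
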