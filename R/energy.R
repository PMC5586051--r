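# Nearest-neighbour RNA/RNA stacking energies (Turner 2004 set, 37 C,
# kcal/mol x 100).  Rows: outer pair (5' base, 3' base); columns: inner
# pair typed in reversed orientation, the standard parameter-table
# convention.  Pair order: CG, GC, GU, UG, AU, UA.  Used by both the
# hairpin folder and the miRNA/target duplex energy model, so energy
# ratios are model-consistent.
PAIR_ORDER <- c("CG", "GC", "GT", "TG", "AT", "TA")

STACK100 <- matrix(c(
  -240, -330, -210, -140, -210, -210,
  -330, -340, -250, -150, -220, -240,
  -210, -250,  130,  -50, -140, -130,
  -140, -150,  -50,   30,  -60, -100,
  -210, -220, -140,  -60, -110,  -90,
  -210, -240, -130, -100,  -90, -130),
  nrow = 6L, byrow = TRUE, dimnames = list(PAIR_ORDER, PAIR_ORDER))
storage.mode(STACK100) <- "integer"

# pair type index (1..6) of bases a over b, 0 if not pairable (DNA
# alphabet, T == U); Watson-Crick pairs plus the G.U wobble
pair_type_idx <- function(a, b) {
  key <- paste0(a, b)
  idx <- match(key, PAIR_ORDER)
  ifelse(is.na(idx), 0L, idx)
}
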