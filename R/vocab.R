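#' Token vocabularies for protein and SMILES sequences
#'
#' A vocabulary is a bijective map between tokens and 1-based integer ids.
#' The five special tokens (PAD, UNK, CLS, SEP, MASK) always occupy the
#' first five ids, in that order, so that downstream code can rely on their
#' positions regardless of the residue or SMILES alphabet behind them.
#'
#' @param tokens Character vector of non-special tokens, in id order.
#' @return An object of class `dti_vocab`: a list with `tokens` (character
#'   vector indexed by id), `ids` (named integer vector), and `specials`
#'   (named integer vector with entries PAD, UNK, CLS, SEP, MASK).
#' @keywords internal
new_vocab <- function(tokens) {
  specials <- c(PAD = 1L, UNK = 2L, CLS = 3L, SEP = 4L, MASK = 5L)
  all_tokens <- c("[PAD]", "[UNK]", "[CLS]", "[SEP]", "[MASK]", tokens)
  if (anyDuplicated(all_tokens)) {
    rlang::abort("vocabulary tokens must be unique")
  }
  ids <- seq_along(all_tokens)
  names(ids) <- all_tokens
  structure(
    list(tokens = all_tokens, ids = ids, specials = specials),
    class = "dti_vocab"
  )
}

#' @export
print.dti_vocab <- function(x, ...) {
  cat("<dti_vocab> ", length(x$tokens), " tokens (5 specials)\n", sep = "")
  invisible(x)
}

#' @export
length.dti_vocab <- function(x) length(x$tokens)

# canonical 20 amino acids plus the ambiguity / rare codes X, U, B, Z, O
PROTEIN_RESIDUES <- c(
  "A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
  "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V",
  "X", "U", "B", "Z", "O"
)

#' Build the protein residue vocabulary
#'
#' Thirty entries: five special tokens plus the 20 canonical amino acids and
#' the five extended single-letter codes (X, U, B, Z, O), matching the
#' convention of large pretrained protein language models so that cached
#' teacher features and student inputs share one token space. Residues not
#' in this alphabet map to UNK; they are never dropped.
#'
#' @return A `dti_vocab` of size 30.
#' @examples
#' v <- build_protein_vocab()
#' length(v)
#' vocab_lookup(v, "A")
#' @export
build_protein_vocab <- function() {
  new_vocab(PROTEIN_RESIDUES)
}

# Default SMILES token alphabet: organic-subset atoms, aromatic forms,
# two-letter halogens, common bracket atoms, bonds, branches, ring-closure
# digits and stereo marks. Out-of-alphabet tokens map to UNK.
SMILES_TOKENS <- c(
  "C", "N", "O", "S", "P", "F", "I", "B",
  "c", "n", "o", "s", "p", "b",
  "Cl", "Br", "Si", "Se", "se",
  "[nH]", "[NH+]", "[NH2+]", "[NH3+]", "[N+]", "[N-]", "[O-]", "[OH+]",
  "[C@H]", "[C@@H]", "[C@]", "[C@@]", "[S+]", "[s+]", "[Se]", "[SeH]",
  "[Na+]", "[Cl-]", "[Br-]", "[H]",
  "(", ")", "=", "#", "-", "+", "/", "\\", ".", ":", "~", "@",
  as.character(0:9), "%10", "%11", "%12"
)

#' Build the SMILES token vocabulary
#'
#' Fixed, self-contained alphabet covering the organic subset, aromatic
#' atoms, two-letter elements, common bracket atoms, bonds, branch and
#' ring-closure symbols. Tokens outside the alphabet map to UNK. A custom
#' alphabet can be supplied for fidelity runs against a pretrained
#' checkpoint's vocabulary.
#'
#' @param tokens Optional character vector overriding the default alphabet.
#' @return A `dti_vocab`.
#' @export
build_smiles_vocab <- function(tokens = SMILES_TOKENS) {
  new_vocab(tokens)
}

#' Look up token ids in a vocabulary
#'
#' @param vocab A `dti_vocab`.
#' @param tokens Character vector of tokens.
#' @return Integer ids; unknown tokens receive the UNK id.
#' @export
vocab_lookup <- function(vocab, tokens) {
  ids <- unname(vocab$ids[tokens])
  ids[is.na(ids)] <- vocab$specials[["UNK"]]
  as.integer(ids)
}

# Atom-level SMILES regex: bracket atoms are single tokens, two-letter
# elements beat one-letter ones, %NN ring closures and stereo marks are
# single tokens. The final "." branch of the alternation is a catch-all so
# no character is ever silently dropped (it becomes UNK at lookup).
SMILES_ATOM_REGEX <- paste0(
  "(\\[[^\\]]*\\]|Br|Cl|Si|Se|se|@@|%\\d{2}|",
  "[A-IK-PR-Za-ik-pr-z]|=|#|\\(|\\)|\\+|-|/|\\\\|\\.|:|~|@|\\?|\\*|\\$|\\d|.)"
)

#' Tokenize a SMILES string at atom level
#'
#' Splits a SMILES string with the standard atom-level regular expression:
#' bracket expressions (e.g. `[nH]`) are single tokens, two-letter elements
#' (`Cl`, `Br`) are recognized before their one-letter prefixes, `%NN` ring
#' closures and `@@` stereo marks are kept whole. Every input character ends
#' up in some token.
#'
#' @param smiles A single SMILES string.
#' @return Character vector of tokens.
#' @examples
#' smiles_atom_tokens("CC(=O)Nc1ccc(O)cc1")
#' smiles_atom_tokens("[nH]1cccc1Cl")
#' @export
smiles_atom_tokens <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) == 1L)
  m <- gregexpr(SMILES_ATOM_REGEX, smiles, perl = TRUE)
  regmatches(smiles, m)[[1]]
}

new_token_seq <- function(token_ids, attention_mask, true_length) {
  structure(
    list(
      token_ids = as.integer(token_ids),
      attention_mask = as.integer(attention_mask),
      true_length = as.integer(true_length)
    ),
    class = "token_seq"
  )
}

#' @export
print.token_seq <- function(x, ...) {
  cat("<token_seq> ", x$true_length, " real tokens in ",
      length(x$token_ids), " slots\n", sep = "")
  invisible(x)
}

# Shared CLS/SEP/PAD assembly. `body_ids` are the content-token ids.
# Contract: the output always has exactly max_len slots; the first token is
# CLS; SEP terminates the sequence when there is room for it; truncation
# keeps a prefix so shorter max_len values are prefixes of longer ones.
assemble_token_seq <- function(body_ids, max_len, vocab) {
  sp <- vocab$specials
  ids <- c(sp[["CLS"]], body_ids)
  if (length(ids) + 1L <= max_len) {
    ids <- c(ids, sp[["SEP"]])
  } else if (length(ids) > max_len) {
    ids <- ids[seq_len(max_len)]
  }
  true_len <- length(ids)
  pad_n <- max_len - true_len
  new_token_seq(
    token_ids = c(ids, rep(sp[["PAD"]], pad_n)),
    attention_mask = c(rep(1L, true_len), rep(0L, pad_n)),
    true_length = true_len
  )
}

#' Tokenize a protein sequence
#'
#' Single-letter residues become one token each; the result is CLS-prefixed,
#' SEP-terminated when there is room, truncated to `max_len` total slots and
#' padded with PAD. Residues outside the 25-letter alphabet map to UNK.
#'
#' @param sequence Amino-acid string (single-letter codes).
#' @param max_len Total token slots including CLS/SEP (default 545, covering
#'   about 95% of protein lengths in common DTI benchmarks).
#' @param vocab Protein vocabulary; defaults to [build_protein_vocab()].
#' @return A `token_seq` with `token_ids`, `attention_mask`, `true_length`.
#' @examples
#' ts <- tokenize_protein("MKV")
#' ts$token_ids[1:6]
#' @export
tokenize_protein <- function(sequence, max_len = 545L,
                             vocab = build_protein_vocab()) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  if (is.na(sequence) || nchar(sequence) == 0L) {
    rlang::abort("protein sequence must be non-empty")
  }
  chars <- strsplit(toupper(sequence), "", fixed = TRUE)[[1]]
  assemble_token_seq(vocab_lookup(vocab, chars), max_len, vocab)
}

#' Tokenize a SMILES string
#'
#' Applies the atom-level regex tokenizer (or a user-supplied tokenizer
#' function for fidelity runs against a pretrained checkpoint), then
#' assembles a CLS-prefixed, SEP-terminated, PAD-filled id sequence of
#' exactly `max_len` slots.
#'
#' @param smiles SMILES string.
#' @param max_len Total token slots including CLS/SEP (default 512).
#' @param vocab SMILES vocabulary; defaults to [build_smiles_vocab()].
#' @param tokenizer Function mapping a SMILES string to a character vector
#'   of tokens; defaults to [smiles_atom_tokens()].
#' @return A `token_seq`.
#' @examples
#' tokenize_smiles("CCO", max_len = 8)$token_ids
#' @export
tokenize_smiles <- function(smiles, max_len = 512L,
                            vocab = build_smiles_vocab(),
                            tokenizer = smiles_atom_tokens) {
  stopifnot(is.character(smiles), length(smiles) == 1L)
  if (is.na(smiles) || nchar(smiles) == 0L) {
    rlang::abort("SMILES string must be non-empty")
  }
  assemble_token_seq(vocab_lookup(vocab, tokenizer(smiles)), max_len, vocab)
}

#' Recover the token string from a token sequence
#'
#' Inverse of tokenization on in-vocabulary inputs: special tokens are
#' dropped and the remaining tokens concatenated.
#'
#' @param tokens A `token_seq` or integer id vector.
#' @param vocab The vocabulary that produced the ids.
#' @return A single string.
#' @export
detokenize <- function(tokens, vocab) {
  ids <- if (inherits(tokens, "token_seq")) tokens$token_ids else as.integer(tokens)
  keep <- !(ids %in% vocab$specials)
  paste(vocab$tokens[ids[keep]], collapse = "")
}
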