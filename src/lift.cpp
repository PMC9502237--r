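#include <Rcpp.h>
using namespace Rcpp;

// CIGAR op codes follow BAM encoding: M=0 I=1 D=2 N=3 S=4 H=5 P=6 ==7 X=8.
static const char OP_CHARS[] = "MIDNSHP=X";

// [[Rcpp::export]]
List cpp_parse_cigar(std::string cigar) {
  std::vector<int> ops, lens;
  size_t i = 0, n = cigar.size();
  while (i < n) {
    if (!isdigit(cigar[i])) stop("malformed CIGAR: %s", cigar);
    long len = 0;
    while (i < n && isdigit(cigar[i])) {
      len = len * 10 + (cigar[i] - '0');
      ++i;
    }
    if (i >= n || len <= 0) stop("malformed CIGAR: %s", cigar);
    const char *p = strchr(OP_CHARS, cigar[i]);
    if (p == NULL || cigar[i] == '\0') stop("malformed CIGAR: %s", cigar);
    ops.push_back((int)(p - OP_CHARS));
    lens.push_back((int)len);
    ++i;
  }
  return List::create(_["ops"] = wrap(ops), _["lens"] = wrap(lens));
}

// [[Rcpp::export]]
std::string cpp_format_cigar(IntegerVector ops, IntegerVector lens) {
  std::string out;
  char buf[16];
  for (int i = 0; i < ops.size(); ++i) {
    snprintf(buf, sizeof(buf), "%d", lens[i]);
    out += buf;
    out += OP_CHARS[ops[i]];
  }
  return out;
}

// Compose a read->source CIGAR with the source->target column map.
//
// Walks the alignment one source base at a time starting at the column of
// source base s_pos. Query-only ops (I/S/H/P) pass through. For each
// reference-consuming base: a both-1 column keeps the op; a src-only
// column (inserted base) turns M/=/X into I and shrinks D/N. Target-only
// columns between consecutive consumed source bases inject D, or extend N
// when the flanking base on either side was consumed by an N op; gap
// columns seen before the first both-1 base precede the lifted start and
// are dropped. Adjacent identical ops merge; zero-length ops are never
// emitted.
//
// Returns mapped=false when no both-1 column is covered (alignment lies
// entirely inside an insertion); t_pos is then the clamped position of the
// next target base after the anchor.
// [[Rcpp::export]]
List cpp_lift_cigar(IntegerVector src_bits, IntegerVector tgt_bits,
                    IntegerVector cum_tgt, IntegerVector sel_src,
                    int s_pos, IntegerVector ops, IntegerVector lens,
                    int tgt_len) {
  std::vector<int> oops, olens;
  auto emit = [&](int op, int len) {
    if (len <= 0) return;
    if (!oops.empty() && oops.back() == op) {
      olens.back() += len;
    } else {
      oops.push_back(op);
      olens.push_back(len);
    }
  };

  int cur_col = sel_src[s_pos];  // sel_src is 0-based per source base
  const int start_col = cur_col;
  int first_both = -1;
  int prev_op = -1;   // op that consumed the previous source base
  bool first = true;

  for (int i = 0; i < ops.size(); ++i) {
    const int op = ops[i], len = lens[i];
    const bool ref_consuming =
        (op == 0 || op == 2 || op == 3 || op == 7 || op == 8);
    if (!ref_consuming) {  // I, S, H, P: untouched
      emit(op, len);
      continue;
    }
    for (int j = 0; j < len; ++j) {
      if (!first) {
        int gap = 0, c = cur_col + 1;
        while (src_bits[c] == 0) {  // tgt-only columns between source bases
          ++gap;
          ++c;
        }
        if (gap > 0 && first_both >= 0) {
          emit((prev_op == 3 || op == 3) ? 3 : 2, gap);
        }
        cur_col = c;
      }
      first = false;
      if (tgt_bits[cur_col] == 1) {
        emit(op, 1);
        if (first_both < 0) first_both = cur_col;
      } else if (op == 0 || op == 7 || op == 8) {
        emit(1, 1);  // read base over an inserted reference base -> I
      }                // D/N over an inserted base: span shrinks
      prev_op = op;
    }
  }

  bool mapped = first_both >= 0;
  int t_pos;
  if (mapped) {
    t_pos = cum_tgt[first_both];
  } else {
    t_pos = cum_tgt[start_col];
    if (t_pos > tgt_len - 1) t_pos = tgt_len - 1;
    if (t_pos < 0) t_pos = 0;
  }
  return List::create(_["mapped"] = mapped, _["t_pos"] = t_pos,
                      _["ops"] = wrap(oops), _["lens"] = wrap(olens));
}
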