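#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Affine-gap local alignment (Smith-Waterman-Gotoh) of short reads against a
// transcript reference. Tie-breaking is fully deterministic: at each cell the
// diagonal move is preferred over a gap in the read (vertical) over a gap in
// the reference (horizontal); among equal-scoring end cells the one with the
// smallest reference coordinate, then smallest read coordinate, wins.
// N never scores as a match, in either sequence.

namespace {

inline int base_code(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return 4;  // N or anything else
  }
}

struct AlnResult {
  double score;
  int ref_start, ref_end;    // 1-based inclusive, 0 when unaligned
  int read_start, read_end;  // 1-based inclusive on the read as given
  int n_mismatch, n_ins, n_del;
  std::vector<int> mismatch_pos;  // reference coordinates of mismatched columns
  std::vector<int> del_pos;       // reference positions aligned to a gap in the read
  std::vector<int> ins_pos;       // reference position after which read bases are inserted
  std::string cigar;
};

// traceback codes for H
enum { TB_STOP = 0, TB_DIAG = 1, TB_UP = 2, TB_LEFT = 3 };

void align_one(const std::string &read, const std::string &ref,
               double match, double mismatch, double gap_open,
               double gap_extend, AlnResult &out) {
  const int m = (int)read.size(), n = (int)ref.size();
  out = AlnResult();
  out.score = 0.0;
  out.ref_start = out.ref_end = out.read_start = out.read_end = 0;
  out.n_mismatch = out.n_ins = out.n_del = 0;
  out.cigar = "*";
  if (m == 0 || n == 0) return;

  std::vector<int> rd(m), rf(n);
  for (int i = 0; i < m; ++i) rd[i] = base_code(read[i]);
  for (int j = 0; j < n; ++j) rf[j] = base_code(ref[j]);

  const double NEG = -1e30;
  const double go_ge = gap_open + gap_extend;
  std::vector<double> Hprev(n + 1, 0.0), Hcur(n + 1, 0.0);
  std::vector<double> Fcol(n + 1, NEG);          // gap in reference (consumes read)
  // packed traceback, (m+1) x (n+1): bits 0-1 H pointer, bit 2 E-extend,
  // bit 3 F-extend
  std::vector<unsigned char> tb((size_t)(m + 1) * (n + 1), TB_STOP);

  double best = 0.0;
  int bi = 0, bj = 0;

  for (int i = 1; i <= m; ++i) {
    double Ecur = NEG;  // gap in read (consumes reference), within row i
    unsigned char *tbrow = &tb[(size_t)i * (n + 1)];
    const double *hp = Hprev.data();
    double *hc = Hcur.data(), *fc = Fcol.data();
    const int rdi = rd[i - 1];
    double hleft = 0.0;  // Hcur[j-1]
    hc[0] = 0.0;
    for (int j = 1; j <= n; ++j) {
      unsigned char cell;
      // E: move left (reference base j aligned to '-')
      double e_open = hleft + go_ge;
      double e_ext = Ecur + gap_extend;
      if (e_ext > e_open) { Ecur = e_ext; cell = 4; }
      else { Ecur = e_open; cell = 0; }
      // F: move up (read base i aligned to '-')
      double f_open = hp[j] + go_ge;
      double f_ext = fc[j] + gap_extend;
      double f;
      if (f_ext > f_open) { f = f_ext; cell |= 8; }
      else { f = f_open; }
      fc[j] = f;
      // H: prefer diagonal, then up, then left
      double s = (rdi == rf[j - 1] && rdi != 4) ? match : mismatch;
      double h = hp[j - 1] + s;
      unsigned char ptr = TB_DIAG;
      if (f > h) { h = f; ptr = TB_UP; }
      if (Ecur > h) { h = Ecur; ptr = TB_LEFT; }
      if (h <= 0.0) { h = 0.0; ptr = TB_STOP; }
      hc[j] = h;
      hleft = h;
      tbrow[j] = cell | ptr;
      if (h > best) { best = h; bi = i; bj = j; }
      // ties: keep the earlier (smaller j, then smaller i) end cell, i.e. do
      // not replace on equality -- j grows within a row, i across rows.
    }
    std::swap(Hprev, Hcur);
  }

  out.score = best;
  if (best <= 0.0) return;

  // traceback from (bi, bj)
  int i = bi, j = bj;
  std::vector<std::pair<char, int> > ops;  // reversed op runs
  unsigned char state = 'H';
  while (i > 0 && j > 0) {
    size_t idx = (size_t)i * (n + 1) + j;
    if (state == 'H') {
      unsigned char p = tb[idx] & 3;
      if (p == TB_STOP) break;
      if (p == TB_DIAG) {
        bool mm = !(rd[i - 1] == rf[j - 1] && rd[i - 1] != 4);
        if (mm) { out.n_mismatch++; out.mismatch_pos.push_back(j); }
        if (!ops.empty() && ops.back().first == 'M') ops.back().second++;
        else ops.push_back(std::make_pair('M', 1));
        --i; --j;
      } else if (p == TB_UP) {
        state = 'F';
      } else {
        state = 'E';
      }
    } else if (state == 'F') {  // gap in reference, consume read base i
      out.n_ins++;
      out.ins_pos.push_back(j);
      if (!ops.empty() && ops.back().first == 'I') ops.back().second++;
      else ops.push_back(std::make_pair('I', 1));
      unsigned char ext = tb[idx] & 8;
      --i;
      if (!ext) state = 'H';
    } else {  // E: gap in read, consume reference base j
      out.n_del++;
      out.del_pos.push_back(j);
      if (!ops.empty() && ops.back().first == 'D') ops.back().second++;
      else ops.push_back(std::make_pair('D', 1));
      unsigned char ext = tb[idx] & 4;
      --j;
      if (!ext) state = 'H';
    }
  }

  out.ref_start = j + 1;
  out.ref_end = bj;
  out.read_start = i + 1;
  out.read_end = bi;

  // CIGAR with soft clips, read orientation as given
  std::string cig;
  char buf[16];
  if (out.read_start > 1) {
    snprintf(buf, sizeof(buf), "%dS", out.read_start - 1);
    cig += buf;
  }
  for (int k = (int)ops.size() - 1; k >= 0; --k) {
    snprintf(buf, sizeof(buf), "%d%c", ops[k].second, ops[k].first);
    cig += buf;
  }
  if (out.read_end < m) {
    snprintf(buf, sizeof(buf), "%dS", m - out.read_end);
    cig += buf;
  }
  out.cigar = cig;
}

}  // namespace

// [[Rcpp::export(name = ".align_batch_cpp")]]
List align_batch_cpp(CharacterVector reads, std::string reference,
                     double match, double mismatch,
                     double gap_open, double gap_extend) {
  const int nr = reads.size();
  NumericVector score(nr);
  IntegerVector ref_start(nr), ref_end(nr), read_start(nr), read_end(nr);
  IntegerVector n_mismatch(nr), n_ins(nr), n_del(nr);
  List mismatch_pos(nr), del_pos(nr), ins_pos(nr);
  CharacterVector cigar(nr);

  AlnResult res;
  for (int k = 0; k < nr; ++k) {
    std::string rd = as<std::string>(reads[k]);
    align_one(rd, reference, match, mismatch, gap_open, gap_extend, res);
    score[k] = res.score;
    ref_start[k] = res.ref_start;
    ref_end[k] = res.ref_end;
    read_start[k] = res.read_start;
    read_end[k] = res.read_end;
    n_mismatch[k] = res.n_mismatch;
    n_ins[k] = res.n_ins;
    n_del[k] = res.n_del;
    // positions were collected during traceback (reversed); sort ascending
    std::sort(res.mismatch_pos.begin(), res.mismatch_pos.end());
    std::sort(res.del_pos.begin(), res.del_pos.end());
    std::sort(res.ins_pos.begin(), res.ins_pos.end());
    mismatch_pos[k] = IntegerVector(res.mismatch_pos.begin(), res.mismatch_pos.end());
    del_pos[k] = IntegerVector(res.del_pos.begin(), res.del_pos.end());
    ins_pos[k] = IntegerVector(res.ins_pos.begin(), res.ins_pos.end());
    cigar[k] = res.cigar;
  }

  return List::create(
      _["score"] = score, _["ref_start"] = ref_start, _["ref_end"] = ref_end,
      _["read_start"] = read_start, _["read_end"] = read_end,
      _["n_mismatch"] = n_mismatch, _["n_ins"] = n_ins, _["n_del"] = n_del,
      _["mismatch_pos"] = mismatch_pos, _["del_pos"] = del_pos,
      _["ins_pos"] = ins_pos, _["cigar"] = cigar);
}
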