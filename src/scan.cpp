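#include <Rcpp.h>
#include <vector>
#include <string>
#include <algorithm>
#include <climits>
#include <cmath>

using namespace Rcpp;

// 2-bit base codes; 4 = anything that is not a plain A/C/G/T. Code 4 never
// matches anything, including itself (N counts as a mismatch, never a
// wildcard). Complement of a proper code is 3 - code.
static inline int base_code(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return 4;
  }
}

static inline char comp_base(char c) {
  switch (c) {
    case 'A': case 'a': return 'T';
    case 'C': case 'c': return 'G';
    case 'G': case 'g': return 'C';
    case 'T': case 't': return 'A';
    default: return 'N';
  }
}

// [[Rcpp::export(name = ".revcomp_cpp")]]
CharacterVector revcomp_cpp(CharacterVector x) {
  R_xlen_t n = x.size();
  CharacterVector out(n);
  std::string r;
  for (R_xlen_t i = 0; i < n; ++i) {
    SEXP s = STRING_ELT(x, i);
    if (s == NA_STRING) { SET_STRING_ELT(out, i, NA_STRING); continue; }
    const char* p = CHAR(s);
    int w = (int)LENGTH(s);
    r.assign(w, 'N');
    for (int j = 0; j < w; ++j) r[j] = comp_base(p[w - 1 - j]);
    SET_STRING_ELT(out, i, Rf_mkCharLen(r.data(), w));
  }
  return out;
}

// encode k-mer from base codes starting at p; false if any non-ACGT base
static inline bool encode_kmer(const int* code, int p, int k, uint64_t* out) {
  uint64_t v = 0;
  for (int i = 0; i < k; ++i) {
    int c = code[p + i];
    if (c > 3) return false;
    v = (v << 2) | (uint64_t)c;
  }
  *out = v;
  return true;
}

struct JuncIndex {
  std::vector<int> code;                       // contig base codes
  int L;                                       // contig length
  int b;                                       // breakpoint offset (0-based)
  std::vector<std::pair<uint64_t, int> > seeds; // sorted (k-mer, offset)
};

// Scan reads against junction contigs with the seed-and-verify decision
// rule. A placement of a read (diagonal d: read base i on contig base d+i)
// qualifies iff the aligned span crosses the breakpoint with >=
// min_overhang aligned bases on each side, covers >= min_aligned_fraction
// of the read, and has <= max_mismatches Hamming mismatches. Seeding uses
// exact k-mers at stride t = g - k + 1, where g is the minimum
// mismatch-free run length guaranteed by pigeonhole in any qualifying
// span; when g < k the scanner evaluates every breakpoint-crossing
// diagonal instead, so decisions never depend on seeding. Returns one row
// per (read, junction) with a qualifying placement: the best one (fewest
// mismatches, then smallest contig start, then forward before reverse
// complement). Columns: read (1-based), junction (1-based), contig_start,
// aligned_length, mismatches, overhang5, overhang3, orient (1 = forward,
// 2 = revcomp).
// [[Rcpp::export(name = ".scan_reads_cpp")]]
IntegerMatrix scan_reads_cpp(CharacterVector reads,
                             List junctions,
                             int min_overhang,
                             int max_mismatches,
                             int seed_length,
                             double min_aligned_fraction,
                             bool both_orientations) {
  const int o = min_overhang, m = max_mismatches, k = seed_length;
  const int nj = junctions.size();
  const R_xlen_t nr = reads.size();

  int max_w = 0;
  for (R_xlen_t i = 0; i < nr; ++i) {
    int w = (int)LENGTH(STRING_ELT(reads, i));
    if (w > max_w) max_w = w;
  }

  std::vector<JuncIndex> idx(nj);
  for (int j = 0; j < nj; ++j) {
    List jn = junctions[j];
    std::string contig = as<std::string>(jn["contig"]);
    JuncIndex& J = idx[j];
    J.L = (int)contig.size();
    J.b = as<int>(jn["breakpoint_offset"]);
    J.code.resize(J.L);
    for (int p = 0; p < J.L; ++p) J.code[p] = base_code(contig[p]);
    int lo = std::max(0, J.b + o - max_w);
    int hi = std::min(J.L, J.b - o + max_w);
    for (int p = lo; p + k <= hi; ++p) {
      uint64_t key;
      if (encode_kmer(J.code.data(), p, k, &key))
        J.seeds.push_back(std::make_pair(key, p));
    }
    std::sort(J.seeds.begin(), J.seeds.end());
  }

  std::vector<int> rows;           // flat result rows, 8 ints each
  std::vector<int> fcode, ccode, dset;
  fcode.reserve(max_w); ccode.reserve(max_w);

  int n_short = 0, n_with_N = 0;

  for (R_xlen_t i = 0; i < nr; ++i) {
    SEXP rs = STRING_ELT(reads, i);
    const char* rp = CHAR(rs);
    const int w = (int)LENGTH(rs);
    bool has_N = false;
    for (int p = 0; p < w; ++p)
      if (base_code(rp[p]) > 3) { has_N = true; break; }
    if (has_N) ++n_with_N;
    if (w < 2 * o) { ++n_short; continue; }   // cannot span

    // pigeonhole seed plan for this read length
    const int S_min = std::max(2 * o,
                               (int)std::ceil(min_aligned_fraction * w));
    const int g = (int)std::ceil((double)(S_min - m) / (double)(m + 1));
    const bool exhaustive = g < k;
    const int stride = exhaustive ? 1 : (g - k + 1);

    fcode.resize(w); ccode.resize(w);
    for (int p = 0; p < w; ++p) fcode[p] = base_code(rp[p]);
    for (int p = 0; p < w; ++p) {
      int c = fcode[w - 1 - p];
      ccode[p] = c > 3 ? 4 : 3 - c;  // reverse complement in code space
    }

    const int n_orient = both_orientations ? 2 : 1;
    for (int oi = 0; oi < n_orient; ++oi) {
      const int* rcode = (oi == 0) ? fcode.data() : ccode.data();

      for (int j = 0; j < nj; ++j) {
        const JuncIndex& J = idx[j];
        const int d_lo = J.b + o - w, d_hi = J.b - o;
        if (d_lo > d_hi) continue;

        dset.clear();
        if (exhaustive) {
          for (int d = d_lo; d <= d_hi; ++d) dset.push_back(d);
        } else {
          for (int q = 0; q + k <= w; q += stride) {
            uint64_t key;
            if (!encode_kmer(rcode, q, k, &key)) continue;
            std::pair<uint64_t, int> probe(key, INT_MIN);
            for (std::vector<std::pair<uint64_t, int> >::const_iterator it =
                   std::lower_bound(J.seeds.begin(), J.seeds.end(), probe);
                 it != J.seeds.end() && it->first == key; ++it) {
              int d = it->second - q;
              if (d >= d_lo && d <= d_hi) dset.push_back(d);
            }
          }
          if (dset.empty()) continue;
          std::sort(dset.begin(), dset.end());
          dset.erase(std::unique(dset.begin(), dset.end()), dset.end());
        }

        int best_mm = -1, best_cs = 0, best_A = 0, best_o5 = 0, best_o3 = 0;
        for (size_t di = 0; di < dset.size(); ++di) {
          const int d = dset[di];
          const int cs = std::max(0, d), ce = std::min(J.L, d + w);
          const int A = ce - cs;
          if ((double)A < min_aligned_fraction * w) continue;
          if (J.b - cs < o || ce - J.b < o) continue;
          int mm = 0;
          for (int p = cs; p < ce; ++p) {
            const int a = rcode[p - d], c = J.code[p];
            if (a != c || a > 3) {
              if (++mm > m) break;
            }
          }
          if (mm > m) continue;
          if (best_mm < 0 || mm < best_mm ||
              (mm == best_mm && cs < best_cs)) {
            best_mm = mm; best_cs = cs; best_A = A;
            best_o5 = J.b - cs; best_o3 = ce - J.b;
          }
        }
        if (best_mm < 0) continue;

        // merge with a hit of the forward orientation, if any
        bool have_prev = false;
        size_t prev = 0;
        if (oi == 1) {
          for (size_t r = rows.size(); r >= 8; r -= 8) {
            if (rows[r - 8] != (int)(i + 1)) break;
            if (rows[r - 7] == j + 1 && rows[r - 1] == 1) {
              prev = r - 8; have_prev = true; break;
            }
          }
        }
        if (have_prev) {
          const int pmm = rows[prev + 4], pcs = rows[prev + 2];
          if (best_mm < pmm || (best_mm == pmm && best_cs < pcs)) {
            rows[prev + 2] = best_cs; rows[prev + 3] = best_A;
            rows[prev + 4] = best_mm; rows[prev + 5] = best_o5;
            rows[prev + 6] = best_o3; rows[prev + 7] = 2;
          }
        } else {
          const int rr[8] = {(int)(i + 1), j + 1, best_cs, best_A, best_mm,
                             best_o5, best_o3, oi + 1};
          rows.insert(rows.end(), rr, rr + 8);
        }
      }
    }
  }

  const int nrow = (int)(rows.size() / 8);
  IntegerMatrix out(nrow, 8);
  for (int r = 0; r < nrow; ++r)
    for (int cidx = 0; cidx < 8; ++cidx)
      out(r, cidx) = rows[r * 8 + cidx];
  colnames(out) = CharacterVector::create("read", "junction", "contig_start",
                                          "aligned_length", "mismatches",
                                          "overhang5", "overhang3", "orient");
  out.attr("n_short") = n_short;
  out.attr("n_with_N") = n_with_N;
  return out;
}

// Substitute ne[i] random bases of reads[i] (positions without replacement,
// replacement base uniform over the three other proper bases; a non-ACGT
// base is replaced by a uniform proper base). Uses the R RNG, so results
// are reproducible under set.seed().
// [[Rcpp::export(name = ".inject_errors_cpp")]]
CharacterVector inject_errors_cpp(CharacterVector reads, IntegerVector ne) {
  static const char B[4] = {'A', 'C', 'G', 'T'};
  R_xlen_t n = reads.size();
  CharacterVector out(n);
  std::vector<int> pos;
  std::string s;
  for (R_xlen_t i = 0; i < n; ++i) {
    if (ne[i] <= 0) { SET_STRING_ELT(out, i, STRING_ELT(reads, i)); continue; }
    s = as<std::string>(reads[i]);
    int w = (int)s.size();
    int e = std::min(ne[i], w);
    pos.clear();
    while ((int)pos.size() < e) {
      int p = (int)(unif_rand() * w);
      if (p >= w) p = w - 1;
      bool dup = false;
      for (size_t q = 0; q < pos.size(); ++q)
        if (pos[q] == p) { dup = true; break; }
      if (!dup) pos.push_back(p);
    }
    for (size_t q = 0; q < pos.size(); ++q) {
      int p = pos[q];
      int cur = base_code(s[p]);
      if (cur > 3) {
        s[p] = B[(int)(unif_rand() * 4) & 3];
      } else {
        int shift = 1 + (int)(unif_rand() * 3);
        if (shift > 3) shift = 3;
        s[p] = B[(cur + shift) % 4];
      }
    }
    SET_STRING_ELT(out, i, Rf_mkCharLen(s.data(), w));
  }
  return out;
}
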