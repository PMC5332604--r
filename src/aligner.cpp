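// Ungapped seed-and-extend local alignment engine used throughout the
// package: nucleotide (blastn-like), protein (blastp-like), six-frame
// translated (tblastx-like) and protein-vs-translated (tblastn-like)
// searches, plus a batched all-against-all routine that reduces HSP sets
// to the genome-wide raw similarity used by the S_G score.
//
// Design: exact-word seeding (4-mer peptide with a two-hit rule on the
// diagonal, 11-mer nucleotide one-hit), ungapped X-drop extension, and
// Karlin-Altschul ungapped statistics for bit scores and E-values. This
// is a desk-scale aligner, deliberately simpler than any full BLAST
// implementation; scoring constants are documented in the R wrappers.

#include <Rcpp.h>
#include <vector>
#include <string>
#include <algorithm>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// alphabets and scoring

// amino-acid order used internally: ARNDCQEGHILKMFPSTWYV + X (20)
static const int AA_N = 21; // 0..19 canonical, 20 = X
static const int AA_X = 20;

// BLOSUM62 (canonical 20 + X row/col)
static const int BLOSUM62[21 * 21] = {
//  A   R   N   D   C   Q   E   G   H   I   L   K   M   F   P   S   T   W   Y   V   X
    4, -1, -2, -2,  0, -1, -1,  0, -2, -1, -1, -1, -1, -2, -1,  1,  0, -3, -2,  0,  0,
   -1,  5,  0, -2, -3,  1,  0, -2,  0, -3, -2,  2, -1, -3, -2, -1, -1, -3, -2, -3, -1,
   -2,  0,  6,  1, -3,  0,  0,  0,  1, -3, -3,  0, -2, -3, -2,  1,  0, -4, -2, -3, -1,
   -2, -2,  1,  6, -3,  0,  2, -1, -1, -3, -4, -1, -3, -3, -1,  0, -1, -4, -3, -3, -1,
    0, -3, -3, -3,  9, -3, -4, -3, -3, -1, -1, -3, -1, -2, -3, -1, -1, -2, -2, -1, -2,
   -1,  1,  0,  0, -3,  5,  2, -2,  0, -3, -2,  1,  0, -3, -1,  0, -1, -2, -1, -2, -1,
   -1,  0,  0,  2, -4,  2,  5, -2,  0, -3, -3,  1, -2, -3, -1,  0, -1, -3, -2, -2, -1,
    0, -2,  0, -1, -3, -2, -2,  6, -2, -4, -4, -2, -3, -3, -2,  0, -2, -2, -3, -3, -1,
   -2,  0,  1, -1, -3,  0,  0, -2,  8, -3, -3, -1, -2, -1, -2, -1, -2, -2,  2, -3, -1,
   -1, -3, -3, -3, -1, -3, -3, -4, -3,  4,  2, -3,  1,  0, -3, -2, -1, -3, -1,  3, -1,
   -1, -2, -3, -4, -1, -2, -3, -4, -3,  2,  4, -2,  2,  0, -3, -2, -1, -2, -1,  1, -1,
   -1,  2,  0, -1, -3,  1,  1, -2, -1, -3, -2,  5, -1, -3, -1,  0, -1, -3, -2, -2, -1,
   -1, -1, -2, -3, -1,  0, -2, -3, -2,  1,  2, -1,  5,  0, -2, -1, -1, -1, -1,  1, -1,
   -2, -3, -3, -3, -2, -3, -3, -3, -1,  0,  0, -3,  0,  6, -4, -2, -2,  1,  3, -1, -1,
   -1, -2, -2, -1, -3, -1, -1, -2, -2, -3, -3, -1, -2, -4,  7, -1, -1, -4, -3, -2, -2,
    1, -1,  1,  0, -1,  0,  0,  0, -1, -2, -2,  0, -1, -2, -1,  4,  1, -3, -2, -2,  0,
    0, -1,  0, -1, -1, -1, -1, -2, -2, -1, -1, -1, -1, -2, -1,  1,  5, -2, -2,  0,  0,
   -3, -3, -4, -4, -2, -2, -3, -2, -2, -3, -2, -3, -1,  1, -4, -3, -2, 11,  2, -3, -2,
   -2, -2, -2, -3, -2, -1, -2, -3,  2, -1, -1, -2, -1,  3, -3, -2, -2,  2,  7, -1, -1,
    0, -3, -3, -3, -1, -2, -2, -3, -3,  3,  1, -2,  1, -1, -2, -2,  0, -3, -1,  4, -1,
    0, -1, -1, -1, -2, -1, -1, -1, -1, -1, -1, -1, -1, -1, -2,  0,  0, -2, -1, -1, -1
};

// genetic code indexed by TCAG-order codon index
static const char CODON_TABLE[] =
    "FFLLSSSSYY**CC*WLLLLPPPPHHQQRRRRIIIMTTTTNNKKSSRRVVVVAAAADDEEGGGG";

static inline int aa_code(char c) {
    switch (c) {
    case 'A': return 0;  case 'R': return 1;  case 'N': return 2;
    case 'D': return 3;  case 'C': return 4;  case 'Q': return 5;
    case 'E': return 6;  case 'G': return 7;  case 'H': return 8;
    case 'I': return 9;  case 'L': return 10; case 'K': return 11;
    case 'M': return 12; case 'F': return 13; case 'P': return 14;
    case 'S': return 15; case 'T': return 16; case 'W': return 17;
    case 'Y': return 18; case 'V': return 19;
    case 'X': case 'B': case 'Z': case 'J': case 'U': case 'O': return AA_X;
    default:  return -1; // '*', '#', anything else: chain break
    }
}

static inline int nt_code(char c) {
    switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;
    }
}

// TCAG index for translation (-1 for ambiguous)
static inline int tcag(char c) {
    switch (c) {
    case 'T': case 't': return 0;
    case 'C': case 'c': return 1;
    case 'A': case 'a': return 2;
    case 'G': case 'g': return 3;
    default: return -1;
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

// ---------------------------------------------------------------------------
// encoded sequence containers

struct FrameSeg {
    int frame;   // +1..+3, -1..-3, or 0 for plain protein/nucleotide
    int start;   // start offset of the segment within the concatenated codes
    int len;     // number of residues in the segment
};

struct Encoded {
    std::vector<int> codes;      // residue codes; -1 = chain break/separator
    std::vector<FrameSeg> segs;  // frame segments (for coordinate mapping)
    int nt_len = 0;              // original nucleotide length (translated modes)
    long letters = 0;            // count of valid residues (for K-A statistics)
};

static Encoded encode_protein(const std::string& s) {
    Encoded e;
    e.codes.reserve(s.size());
    for (char c : s) e.codes.push_back(aa_code(c));
    FrameSeg fs; fs.frame = 0; fs.start = 0; fs.len = (int)s.size();
    e.segs.push_back(fs);
    for (int c : e.codes) if (c >= 0) e.letters++;
    return e;
}

static Encoded encode_nucleotide(const std::string& s) {
    Encoded e;
    e.codes.reserve(s.size());
    for (char c : s) e.codes.push_back(nt_code(c));
    FrameSeg fs; fs.frame = 1; fs.start = 0; fs.len = (int)s.size();
    e.segs.push_back(fs);
    e.nt_len = (int)s.size();
    for (int c : e.codes) if (c >= 0) e.letters++;
    return e;
}

static std::string revcomp(const std::string& s) {
    std::string r(s.size(), 'N');
    for (size_t i = 0; i < s.size(); ++i) r[i] = comp_base(s[s.size() - 1 - i]);
    return r;
}

// translate one frame (fr = 1..3) of s into aa codes
static void translate_frame(const std::string& s, int fr, std::vector<int>& out) {
    int L = (int)s.size();
    for (int i = fr - 1; i + 2 < L; i += 3) {
        int a = tcag(s[i]), b = tcag(s[i + 1]), c = tcag(s[i + 2]);
        if (a < 0 || b < 0 || c < 0) { out.push_back(AA_X); continue; }
        char aa = CODON_TABLE[(a << 4) | (b << 2) | c];
        out.push_back(aa == '*' ? -1 : aa_code(aa)); // stops break chains
    }
}

// six-frame translation into one concatenated code vector with separators
static Encoded encode_translated(const std::string& s) {
    Encoded e;
    e.nt_len = (int)s.size();
    std::string rc = revcomp(s);
    e.codes.reserve(2 * s.size() + 8);
    const int frames[6] = { 1, 2, 3, -1, -2, -3 };
    for (int k = 0; k < 6; ++k) {
        if (k > 0) e.codes.push_back(-1); // separator
        FrameSeg fs;
        fs.frame = frames[k];
        fs.start = (int)e.codes.size();
        size_t before = e.codes.size();
        translate_frame(frames[k] > 0 ? s : rc, std::abs(frames[k]), e.codes);
        fs.len = (int)(e.codes.size() - before);
        e.segs.push_back(fs);
    }
    for (int c : e.codes) if (c >= 0) e.letters++;
    return e;
}

// map a [lo,hi] residue range in concatenated coords back to 1-based
// nucleotide/protein coordinates; for negative frames start > end.
static void seg_coords(const Encoded& e, int lo, int hi,
                       int& start, int& end, int& frame) {
    // locate the segment containing lo (alignments never span separators)
    const FrameSeg* seg = &e.segs[0];
    for (const FrameSeg& fs : e.segs)
        if (lo >= fs.start && lo < fs.start + fs.len) { seg = &fs; break; }
    int p0 = lo - seg->start, p1 = hi - seg->start; // 0-based within frame
    frame = seg->frame;
    if (frame == 0) {                 // protein
        start = p0 + 1; end = p1 + 1;
    } else if (e.nt_len > 0 && std::abs(frame) >= 1 && e.segs.size() > 1) {
        int f = std::abs(frame);
        int ntlo = (f - 1) + 3 * p0;          // 0-based on (rc-)strand
        int nthi = (f - 1) + 3 * p1 + 2;
        if (frame > 0) { start = ntlo + 1; end = nthi + 1; }
        else { start = e.nt_len - ntlo; end = e.nt_len - nthi; } // start > end
    } else {                          // plain nucleotide
        start = p0 + 1; end = p1 + 1;
    }
}

// ---------------------------------------------------------------------------
// seeding and extension

struct Scoring {
    bool protein;      // BLOSUM62 vs +1/-2
    int word;          // seed length
    bool twohit;       // two-hit rule on the diagonal
    int window;        // two-hit max distance
    double xdrop;      // X-drop (raw score units)
    double lambda, K;  // Karlin-Altschul ungapped parameters
};

static inline int score_pair(const Scoring& sc, int a, int b) {
    if (sc.protein) return BLOSUM62[a * AA_N + b];
    return a == b ? 1 : -2;
}

struct Hit {
    int qs, qe, ss, se;   // 0-based inclusive, concatenated coords
    int matches, len;
    double raw;
};

struct SeedIndex {
    int word, alph;
    long tab;
    std::vector<int32_t> heads, nxt;
    void build(const std::vector<int>& codes, int word_, int alph_) {
        word = word_; alph = alph_;
        tab = 1;
        for (int i = 0; i < word; ++i) tab *= alph;
        heads.assign(tab, -1);
        nxt.assign(codes.size(), -1);
        long code = 0; int run = 0;
        for (size_t i = 0; i < codes.size(); ++i) {
            int c = codes[i];
            if (c < 0 || c >= alph) { run = 0; code = 0; continue; }
            code = (code * alph + c) % tab;
            if (++run >= word) {
                int pos = (int)i - word + 1;
                nxt[pos] = heads[code];
                heads[code] = pos;
            }
        }
    }
};

// scratch arrays reused across pairs (stamped to avoid O(n) resets)
struct Scratch {
    std::vector<int> diag_end, diag_end_stamp, diag_hit, diag_hit_stamp;
    int stamp = 0;
    void ensure(size_t n) {
        if (diag_end.size() < n) {
            diag_end.resize(n); diag_end_stamp.assign(n, -1);
            diag_hit.resize(n); diag_hit_stamp.assign(n, -1);
        }
    }
};

static Hit extend_hit(const Scoring& sc, const std::vector<int>& q,
                      const std::vector<int>& s, int qp, int sp) {
    int W = sc.word;
    double cur = 0;
    for (int k = 0; k < W; ++k) cur += score_pair(sc, q[qp + k], s[sp + k]);
    double best = cur;
    int bqe = qp + W - 1, bse = sp + W - 1;
    int i = qp + W, j = sp + W, qn = (int)q.size(), sn = (int)s.size();
    while (i < qn && j < sn) {
        int a = q[i], b = s[j];
        if (a < 0 || b < 0) break;
        cur += score_pair(sc, a, b);
        if (cur > best) { best = cur; bqe = i; bse = j; }
        else if (best - cur > sc.xdrop) break;
        ++i; ++j;
    }
    double curl = 0, bestl = 0;
    int bqs = qp, bss = sp;
    i = qp - 1; j = sp - 1;
    while (i >= 0 && j >= 0) {
        int a = q[i], b = s[j];
        if (a < 0 || b < 0) break;
        curl += score_pair(sc, a, b);
        if (curl > bestl) { bestl = curl; bqs = i; bss = j; }
        else if (bestl - curl > sc.xdrop) break;
        --i; --j;
    }
    Hit h;
    h.qs = bqs; h.qe = bqe; h.ss = bss; h.se = bse;
    h.raw = best + bestl;
    h.len = bqe - bqs + 1;
    h.matches = 0;
    for (int k = 0; k < h.len; ++k)
        if (q[bqs + k] == s[bss + k] && q[bqs + k] >= 0) h.matches++;
    return h;
}

// scan one query against an indexed subject, appending passing hits
static void scan_pair(const Scoring& sc, const std::vector<int>& q,
                      const std::vector<int>& s, const SeedIndex& idx,
                      double min_raw, Scratch& scr, std::vector<Hit>& out) {
    scr.ensure(q.size() + s.size() + 2);
    int stamp = ++scr.stamp;
    int W = sc.word, alph = idx.alph;
    long tab = idx.tab, code = 0;
    int run = 0, qn = (int)q.size(), sn = (int)s.size();
    for (int i = 0; i < qn; ++i) {
        int c = q[i];
        if (c < 0 || c >= alph) { run = 0; code = 0; continue; }
        code = (code * alph + c) % tab;
        if (++run < W) continue;
        int qp = i - W + 1;
        for (int sp = idx.heads[code]; sp >= 0; sp = idx.nxt[sp]) {
            int diag = qp - sp + sn;
            if (scr.diag_end_stamp[diag] == stamp && qp <= scr.diag_end[diag])
                continue;
            if (sc.twohit) {
                // two non-overlapping hits on the diagonal within the
                // window trigger extension; overlapping hits do not
                // advance the stored hit
                bool fire = false;
                if (scr.diag_hit_stamp[diag] == stamp) {
                    int gap = qp - scr.diag_hit[diag];
                    if (gap >= W) {
                        if (gap <= sc.window) fire = true;
                        scr.diag_hit[diag] = qp;
                    }
                } else {
                    scr.diag_hit[diag] = qp;
                    scr.diag_hit_stamp[diag] = stamp;
                }
                if (!fire) continue;
            }
            Hit h = extend_hit(sc, q, s, qp, sp);
            scr.diag_end[diag] = h.qe;
            scr.diag_end_stamp[diag] = stamp;
            if (h.raw >= min_raw) out.push_back(h);
        }
    }
}

static Scoring make_scoring(bool protein) {
    Scoring sc;
    sc.protein = protein;
    if (protein) {
        sc.word = 4; sc.twohit = true; sc.window = 40; sc.xdrop = 20;
        sc.lambda = 0.3176; sc.K = 0.134; // ungapped BLOSUM62
    } else {
        sc.word = 11; sc.twohit = false; sc.window = 0; sc.xdrop = 16;
        sc.lambda = 1.3327; sc.K = 0.621; // ungapped +1/-2
    }
    return sc;
}

static inline double bit_score(const Scoring& sc, double raw) {
    return (sc.lambda * raw - std::log(sc.K)) / M_LN2;
}

// minimum raw score for E-value <= emax over search space m*n
static inline double min_raw_for(const Scoring& sc, long m, long n, double emax) {
    if (m < 1) m = 1;
    if (n < 1) n = 1;
    double bits = std::log2((double)m * (double)n / emax);
    if (bits < 0) bits = 0;
    return (bits * M_LN2 + std::log(sc.K)) / sc.lambda;
}

// ---------------------------------------------------------------------------
// exported: generic search

// mode: "blastp" (protein/protein), "blastn" (nt/nt, both strands),
//       "tblastx" (nt/nt, translated), "tblastn" (protein vs translated nt)
// [[Rcpp::export(name = ".cpp_search")]]
DataFrame cpp_search(CharacterVector queries, CharacterVector subjects,
                     std::string mode, double evalue_max = 1e-3,
                     int max_hits_per_pair = 100000) {
    bool q_prot, s_prot, q_trans = false, s_trans = false;
    if (mode == "blastp") { q_prot = s_prot = true; }
    else if (mode == "blastn") { q_prot = s_prot = false; }
    else if (mode == "tblastx") { q_prot = s_prot = true; q_trans = s_trans = true; }
    else if (mode == "tblastn") { q_prot = s_prot = true; s_trans = true; }
    else stop("unknown mode: " + mode);

    Scoring sc = make_scoring(s_prot);

    int nq = queries.size(), ns = subjects.size();
    std::vector<Encoded> qe(nq);
    for (int i = 0; i < nq; ++i) {
        std::string s = as<std::string>(queries[i]);
        qe[i] = q_trans ? encode_translated(s)
              : (q_prot ? encode_protein(s) : encode_nucleotide(s));
    }
    // blastn scans the reverse-complemented query as a second pass
    std::vector<Encoded> qrc;
    if (mode == "blastn") {
        qrc.resize(nq);
        for (int i = 0; i < nq; ++i)
            qrc[i] = encode_nucleotide(revcomp(as<std::string>(queries[i])));
    }

    std::vector<int> o_q, o_s, o_qs, o_qe, o_ss, o_se, o_qf, o_sf, o_len,
        o_match, o_qlen, o_slen;
    std::vector<double> o_raw, o_bit, o_eval, o_ident;

    Scratch scr;
    SeedIndex idx;
    std::vector<Hit> hits;
    for (int j = 0; j < ns; ++j) {
        std::string ss = as<std::string>(subjects[j]);
        Encoded se = s_trans ? encode_translated(ss)
                   : (s_prot ? encode_protein(ss) : encode_nucleotide(ss));
        idx.build(se.codes, sc.word, sc.protein ? 20 : 4);
        int s_units = s_trans ? se.nt_len : (int)ss.size();
        for (int i = 0; i < nq; ++i) {
            for (int pass = 0; pass < (mode == "blastn" ? 2 : 1); ++pass) {
                const Encoded& Q = (pass == 0) ? qe[i] : qrc[i];
                double min_raw = min_raw_for(sc, Q.letters, se.letters, evalue_max);
                hits.clear();
                scan_pair(sc, Q.codes, se.codes, idx, min_raw, scr, hits);
                if ((int)hits.size() > max_hits_per_pair)
                    hits.resize(max_hits_per_pair);
                for (const Hit& h : hits) {
                    int qs1, qe1, ss1, se1, qf, sf;
                    seg_coords(Q, h.qs, h.qe, qs1, qe1, qf);
                    seg_coords(se, h.ss, h.se, ss1, se1, sf);
                    if (pass == 1) {
                        // hit found on revcomp(query): report plus-strand
                        // query coords against the minus strand of subject
                        int L = Q.nt_len > 0 ? Q.nt_len : (int)Q.codes.size();
                        int nqs = L - qe1 + 1, nqe = L - qs1 + 1;
                        qs1 = nqs; qe1 = nqe;
                        std::swap(ss1, se1);
                        sf = -1; qf = 1;
                    }
                    double bit = bit_score(sc, h.raw);
                    double ev = (double)Q.letters * (double)se.letters *
                        std::pow(2.0, -bit);
                    o_q.push_back(i + 1); o_s.push_back(j + 1);
                    o_qs.push_back(qs1); o_qe.push_back(qe1);
                    o_ss.push_back(ss1); o_se.push_back(se1);
                    o_qf.push_back(q_trans || mode == "blastn" ? qf : 0);
                    o_sf.push_back(s_trans || mode == "blastn" ? sf : 0);
                    o_len.push_back(h.len);
                    o_match.push_back(h.matches);
                    o_ident.push_back(h.len > 0 ? (double)h.matches / h.len : 0.0);
                    o_raw.push_back(h.raw);
                    o_bit.push_back(bit);
                    o_eval.push_back(ev);
                    int qunits = (q_trans || mode == "blastn")
                        ? (Q.nt_len > 0 ? Q.nt_len : (int)Q.codes.size())
                        : (int)qe[i].codes.size();
                    o_qlen.push_back(qunits);
                    o_slen.push_back(s_prot && !s_trans ? (int)se.codes.size()
                                                        : s_units);
                }
            }
        }
    }
    return DataFrame::create(
        _["query"] = o_q, _["subject"] = o_s,
        _["qstart"] = o_qs, _["qend"] = o_qe,
        _["sstart"] = o_ss, _["send"] = o_se,
        _["qframe"] = o_qf, _["sframe"] = o_sf,
        _["length"] = o_len, _["matches"] = o_match,
        _["identity"] = o_ident, _["raw"] = o_raw,
        _["bitscore"] = o_bit, _["evalue"] = o_eval,
        _["qlen"] = o_qlen, _["slen"] = o_slen);
}

// ---------------------------------------------------------------------------
// exported: all-against-all raw similarity (translated)

// Greedy HSP tiling: select HSPs by descending bit score, discard any HSP
// whose query-interval overlap with an already selected HSP exceeds half
// its own length; return the summed bit scores.
struct TileHsp { int lo, hi; double bit; };

static double tile_sum(std::vector<TileHsp>& v) {
    std::sort(v.begin(), v.end(), [](const TileHsp& a, const TileHsp& b) {
        if (a.bit != b.bit) return a.bit > b.bit;
        if (a.lo != b.lo) return a.lo < b.lo;
        return a.hi < b.hi;
    });
    std::vector<const TileHsp*> sel;
    double total = 0;
    for (const TileHsp& h : v) {
        int len = h.hi - h.lo + 1;
        bool ok = true;
        for (const TileHsp* s : sel) {
            int ov = std::min(h.hi, s->hi) - std::max(h.lo, s->lo) + 1;
            if (ov > 0 && 2 * ov > len) { ok = false; break; }
        }
        if (ok) { sel.push_back(&h); total += h.bit; }
    }
    return total;
}

// raw[i][j] = tiled bit-score sum with genome i as query, j as subject
// (six-frame translated search). S_G is assembled in R.
// [[Rcpp::export(name = ".cpp_sg_raw")]]
NumericMatrix cpp_sg_raw(CharacterVector seqs, double evalue_max = 1e-3) {
    int n = seqs.size();
    Scoring sc = make_scoring(true);
    std::vector<Encoded> enc(n);
    for (int i = 0; i < n; ++i)
        enc[i] = encode_translated(as<std::string>(seqs[i]));

    NumericMatrix raw(n, n);
    Scratch scr;
    SeedIndex idx;
    std::vector<Hit> hits;
    std::vector<TileHsp> tiles;
    for (int j = 0; j < n; ++j) {
        idx.build(enc[j].codes, sc.word, 20);
        for (int i = 0; i < n; ++i) {
            double min_raw =
                min_raw_for(sc, enc[i].letters, enc[j].letters, evalue_max);
            hits.clear();
            scan_pair(sc, enc[i].codes, enc[j].codes, idx, min_raw, scr, hits);
            tiles.clear();
            tiles.reserve(hits.size());
            for (const Hit& h : hits) {
                int qs1, qe1, qf;
                seg_coords(enc[i], h.qs, h.qe, qs1, qe1, qf);
                TileHsp t;
                t.lo = std::min(qs1, qe1);
                t.hi = std::max(qs1, qe1);
                t.bit = bit_score(sc, h.raw);
                tiles.push_back(t);
            }
            raw(i, j) = tile_sum(tiles);
        }
        Rcpp::checkUserInterrupt();
    }
    return raw;
}
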