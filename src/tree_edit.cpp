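// Unit-cost tree edit distance between RNA secondary structures.
//
// A dot-bracket structure is encoded as an ordered rooted tree: one node
// per base pair, one leaf per unpaired base, plus a virtual root holding
// the external elements. Edit operations are node insertion and deletion
// at unit cost; nodes match only within their own type (pair with pair,
// unpaired with unpaired), so a cross-type "relabel" costs the same as a
// delete plus an insert. Computed with the Zhang-Shasha key-root dynamic
// program.

#include <Rcpp.h>
#include <vector>
#include <string>
#include <algorithm>

namespace {

struct Tree {
  // postorder arrays
  std::vector<int> type;  // 0 = unpaired leaf, 1 = pair, 2 = virtual root
  std::vector<int> lml;   // leftmost leaf descendant (postorder index)
  std::vector<int> keyroots;
};

// parse dot-bracket into postorder arrays directly
Tree parse(const std::string& db) {
  struct Node { int type; std::vector<int> kids; };
  std::vector<Node> nodes;
  std::vector<int> stack;
  nodes.push_back({2, {}});  // virtual root, index 0
  stack.push_back(0);
  for (char c : db) {
    if (c == '(') {
      nodes.push_back({1, {}});
      nodes[stack.back()].kids.push_back((int)nodes.size() - 1);
      stack.push_back((int)nodes.size() - 1);
    } else if (c == ')') {
      if (stack.size() < 2) Rcpp::stop("unbalanced structure");
      stack.pop_back();
    } else {
      nodes.push_back({0, {}});
      nodes[stack.back()].kids.push_back((int)nodes.size() - 1);
    }
  }
  if (stack.size() != 1) Rcpp::stop("unbalanced structure");

  Tree t;
  int n = (int)nodes.size();
  t.type.reserve(n);
  t.lml.reserve(n);
  // iterative postorder
  std::vector<int> post(n, -1);
  std::vector<std::pair<int, size_t>> st;
  st.push_back({0, 0});
  while (!st.empty()) {
    auto& top = st.back();
    if (top.second < nodes[top.first].kids.size()) {
      int child = nodes[top.first].kids[top.second++];
      st.push_back({child, 0});
    } else {
      int id = top.first;
      st.pop_back();
      int idx = (int)t.type.size();
      post[id] = idx;
      t.type.push_back(nodes[id].type);
      if (nodes[id].kids.empty()) {
        t.lml.push_back(idx);
      } else {
        t.lml.push_back(t.lml[post[nodes[id].kids.front()]]);
      }
    }
  }
  // keyroots: highest postorder node for each distinct leftmost leaf
  std::vector<int> seen;
  for (int i = n - 1; i >= 0; --i) {
    if (std::find(seen.begin(), seen.end(), t.lml[i]) == seen.end()) {
      t.keyroots.push_back(i);
      seen.push_back(t.lml[i]);
    }
  }
  std::sort(t.keyroots.begin(), t.keyroots.end());
  return t;
}

inline int relabel(int a, int b) { return a == b ? 0 : 2; }

int zhang_shasha(const Tree& A, const Tree& B) {
  int n = (int)A.type.size(), m = (int)B.type.size();
  std::vector<std::vector<int>> td(n, std::vector<int>(m, 0));
  // forest distance scratch, offset by leftmost leaves
  std::vector<std::vector<int>> fd(n + 1, std::vector<int>(m + 1, 0));

  for (int ki : A.keyroots) {
    for (int kj : B.keyroots) {
      int li = A.lml[ki], lj = B.lml[kj];
      fd[li][lj] = 0;  // index shift: fd[i+1][j+1] holds forests l..i, l..j
      for (int i = li; i <= ki; ++i) fd[i + 1][lj] = fd[i][lj] + 1;
      for (int j = lj; j <= kj; ++j) fd[li][j + 1] = fd[li][j] + 1;
      for (int i = li; i <= ki; ++i) {
        for (int j = lj; j <= kj; ++j) {
          if (A.lml[i] == li && B.lml[j] == lj) {
            int d = std::min({fd[i][j + 1] + 1, fd[i + 1][j] + 1,
                              fd[i][j] + relabel(A.type[i], B.type[j])});
            fd[i + 1][j + 1] = d;
            td[i][j] = d;
          } else {
            fd[i + 1][j + 1] =
                std::min({fd[i][j + 1] + 1, fd[i + 1][j] + 1,
                          fd[A.lml[i]][B.lml[j]] + td[i][j]});
          }
        }
      }
    }
  }
  return td[n - 1][m - 1];
}

}  // namespace

// [[Rcpp::export(name = ".tree_edit_cpp")]]
int tree_edit_cpp(std::string struct1, std::string struct2) {
  Tree a = parse(struct1);
  Tree b = parse(struct2);
  return zhang_shasha(a, b);
}
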