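#!/usr/bin/env python
"""Regenerate the featurization oracle fixture.

Reads canonical SMILES (one per line) from stdin and writes per-atom
features perceived by RDKit as CSV to stdout:
  smiles,atom,atomic_number,degree,num_hydrogens,implicit_valence,is_aromatic
Atom indices are 1-based in order of appearance in the SMILES string.
"""
import sys
from rdkit import Chem

print("smiles,atom,atomic_number,degree,num_hydrogens,implicit_valence,is_aromatic")
for line in sys.stdin:
    smi = line.strip()
    if not smi:
        continue
    mol = Chem.MolFromSmiles(smi)
    if mol is None:
        sys.stderr.write("unparseable: %s\n" % smi)
        sys.exit(1)
    for a in mol.GetAtoms():
        print("%s,%d,%d,%d,%d,%d,%d" % (
            smi, a.GetIdx() + 1, a.GetAtomicNum(), a.GetDegree(),
            a.GetTotalNumHs(), a.GetImplicitValence(), int(a.GetIsAromatic())))
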