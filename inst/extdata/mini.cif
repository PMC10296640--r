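data_mini
#
# Hand-written miniature mmCIF mirroring chain A of mini.pdb
#
loop_
_atom_site.group_PDB
_atom_site.id
_atom_site.type_symbol
_atom_site.label_atom_id
_atom_site.label_alt_id
_atom_site.label_comp_id
_atom_site.label_asym_id
_atom_site.label_seq_id
_atom_site.pdbx_PDB_ins_code
_atom_site.Cartn_x
_atom_site.Cartn_y
_atom_site.Cartn_z
_atom_site.occupancy
_atom_site.B_iso_or_equiv
_atom_site.auth_seq_id
_atom_site.auth_comp_id
_atom_site.auth_asym_id
_atom_site.auth_atom_id
_atom_site.pdbx_PDB_model_num
ATOM 1  N N  . ALA A 1 ? 0.000 0.000 0.000 1.00 10.00 1 ALA A N  1
ATOM 2  C CA . ALA A 1 ? 1.460 0.000 0.000 1.00 11.20 1 ALA A CA 1
ATOM 3  C C  . ALA A 1 ? 2.000 1.400 0.000 1.00 9.80  1 ALA A C  1
ATOM 4  O O  . ALA A 1 ? 1.400 2.400 0.000 1.00 12.00 1 ALA A O  1
ATOM 5  C CB . ALA A 1 ? 2.000 -0.800 1.200 1.00 13.10 1 ALA A CB 1
ATOM 6  H HB1 . ALA A 1 ? 2.500 -1.500 1.700 1.00 13.10 1 ALA A HB1 1
ATOM 7  N N  . GLY A 2 ? 3.300 1.500 0.000 1.00 14.00 2 GLY A N  1
ATOM 8  C CA . GLY A 2 ? 4.000 2.700 0.000 1.00 15.30 2 GLY A CA 1
ATOM 9  C C  . GLY A 2 ? 5.500 2.600 0.000 1.00 13.90 2 GLY A C  1
ATOM 10 O O  . GLY A 2 ? 6.100 1.500 0.000 1.00 16.00 2 GLY A O  1
ATOM 11 N N  . SER A 3 ? 6.100 3.700 0.000 1.00 15.00 3 SER A N  1
ATOM 12 C CA . SER A 3 ? 7.500 3.800 0.200 1.00 16.10 3 SER A CA 1
ATOM 13 C C  . SER A 3 ? 8.200 5.000 0.600 1.00 14.70 3 SER A C  1
ATOM 14 O O  . SER A 3 ? 7.600 6.100 0.600 1.00 17.40 3 SER A O  1
ATOM 15 C CB . SER A 3 ? 8.000 2.900 1.300 1.00 18.00 3 SER A CB 1
ATOM 16 O OG A SER A 3 ? 8.400 1.700 0.900 0.60 19.00 3 SER A OG 1
ATOM 17 O OG B SER A 3 ? 9.400 3.200 1.600 0.40 19.50 3 SER A OG 1
HETATM 18 O O . HOH A 101 ? 20.000 20.000 20.000 1.00 30.00 101 HOH A O 1
#
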