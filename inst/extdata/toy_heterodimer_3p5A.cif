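data_TOYHET
#
_entry.id TOYHET
#
loop_
_entity_poly.entity_id
_entity_poly.type
_entity_poly.pdbx_seq_one_letter_code_can
1 'polypeptide(L)' ASE
2 'polypeptide(L)' MKA
#
loop_
_pdbx_struct_assembly_gen.assembly_id
_pdbx_struct_assembly_gen.oper_expression
_pdbx_struct_assembly_gen.asym_id_list
1 '1' A,B
#
loop_
_pdbx_struct_oper_list.id
_pdbx_struct_oper_list.type
_pdbx_struct_oper_list.matrix[1][1]
_pdbx_struct_oper_list.matrix[1][2]
_pdbx_struct_oper_list.matrix[1][3]
_pdbx_struct_oper_list.vector[1]
_pdbx_struct_oper_list.matrix[2][1]
_pdbx_struct_oper_list.matrix[2][2]
_pdbx_struct_oper_list.matrix[2][3]
_pdbx_struct_oper_list.vector[2]
_pdbx_struct_oper_list.matrix[3][1]
_pdbx_struct_oper_list.matrix[3][2]
_pdbx_struct_oper_list.matrix[3][3]
_pdbx_struct_oper_list.vector[3]
1 'point symmetry operation' 1 0 0 0 0 1 0 0 0 0 1 0
#
loop_
_atom_site.group_PDB
_atom_site.id
_atom_site.type_symbol
_atom_site.label_atom_id
_atom_site.label_alt_id
_atom_site.label_comp_id
_atom_site.label_asym_id
_atom_site.label_entity_id
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
_atom_site.pdbx_PDB_model_num
ATOM 1 N N . ALA A 1 1 ? 0.000 0.000 0.000 1.00 0.00 1 ALA A 1
ATOM 2 C CA . ALA A 1 1 ? 1.458 0.000 0.000 1.00 0.00 1 ALA A 1
ATOM 3 C C . ALA A 1 1 ? 2.009 1.420 0.000 1.00 0.00 1 ALA A 1
ATOM 4 O O . ALA A 1 1 ? 1.600 2.540 0.000 1.00 0.00 1 ALA A 1
ATOM 5 N N . SER A 1 2 ? 3.800 0.000 0.000 1.00 0.00 2 SER A 1
ATOM 6 C CA . SER A 1 2 ? 5.258 0.000 0.000 1.00 0.00 2 SER A 1
ATOM 7 C C . SER A 1 2 ? 5.809 1.420 0.000 1.00 0.00 2 SER A 1
ATOM 8 O O . SER A 1 2 ? 5.400 2.540 0.000 1.00 0.00 2 SER A 1
ATOM 9 N N . GLU A 1 3 ? 7.600 0.000 0.000 1.00 0.00 3 GLU A 1
ATOM 10 C CA . GLU A 1 3 ? 9.058 0.000 0.000 1.00 0.00 3 GLU A 1
ATOM 11 C C . GLU A 1 3 ? 9.609 1.420 0.000 1.00 0.00 3 GLU A 1
ATOM 12 O O . GLU A 1 3 ? 9.200 2.540 0.000 1.00 0.00 3 GLU A 1
ATOM 13 N N . MET B 2 1 ? 2.409 9.520 -3.200 1.00 0.00 1 MET B 1
ATOM 14 C CA . MET B 2 1 ? 3.867 9.520 -3.200 1.00 0.00 1 MET B 1
ATOM 15 C C . MET B 2 1 ? 4.418 10.940 -3.200 1.00 0.00 1 MET B 1
ATOM 16 O O . MET B 2 1 ? 4.009 12.060 -3.200 1.00 0.00 1 MET B 1
ATOM 17 N N . LYS B 2 2 ? 6.209 9.520 -3.200 1.00 0.00 2 LYS B 1
ATOM 18 C CA . LYS B 2 2 ? 7.667 9.520 -3.200 1.00 0.00 2 LYS B 1
ATOM 19 C C . LYS B 2 2 ? 8.218 10.940 -3.200 1.00 0.00 2 LYS B 1
ATOM 20 O O . LYS B 2 2 ? 7.809 12.060 -3.200 1.00 0.00 2 LYS B 1
ATOM 21 C CB . LYS B 2 2 ? 7.409 8.420 -2.400 1.00 0.00 2 LYS B 1
ATOM 22 C CG . LYS B 2 2 ? 8.009 7.420 -1.700 1.00 0.00 2 LYS B 1
ATOM 23 C CD . LYS B 2 2 ? 8.609 6.420 -1.100 1.00 0.00 2 LYS B 1
ATOM 24 C CE . LYS B 2 2 ? 9.209 5.620 -0.500 1.00 0.00 2 LYS B 1
ATOM 25 N NZ . LYS B 2 2 ? 9.609 4.920 0.000 1.00 0.00 2 LYS B 1
ATOM 26 N N . ALA B 2 3 ? 10.009 9.520 -3.200 1.00 0.00 3 ALA B 1
ATOM 27 C CA . ALA B 2 3 ? 11.467 9.520 -3.200 1.00 0.00 3 ALA B 1
ATOM 28 C C . ALA B 2 3 ? 12.018 10.940 -3.200 1.00 0.00 3 ALA B 1
ATOM 29 O O . ALA B 2 3 ? 11.609 12.060 -3.200 1.00 0.00 3 ALA B 1
#
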