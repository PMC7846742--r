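data_TOYHOM
#
_entry.id TOYHOM
#
loop_
_entity_poly.entity_id
_entity_poly.type
_entity_poly.pdbx_seq_one_letter_code_can
1 'polypeptide(L)' MKAE
#
loop_
_pdbx_struct_assembly_gen.assembly_id
_pdbx_struct_assembly_gen.oper_expression
_pdbx_struct_assembly_gen.asym_id_list
1 '1,2' A
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
2 'point symmetry operation' -1 0 0 20.609 0 -1 0 3.82 0 0 1 -3.2
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
ATOM 1 N N . MET A 1 1 ? 0.000 0.000 0.000 1.00 0.00 1 MET A 1
ATOM 2 C CA . MET A 1 1 ? 1.458 0.000 0.000 1.00 0.00 1 MET A 1
ATOM 3 C C . MET A 1 1 ? 2.009 1.420 0.000 1.00 0.00 1 MET A 1
ATOM 4 O O . MET A 1 1 ? 1.600 2.540 0.000 1.00 0.00 1 MET A 1
ATOM 5 N N . LYS A 1 2 ? 3.800 0.000 0.000 1.00 0.00 2 LYS A 1
ATOM 6 C CA . LYS A 1 2 ? 5.258 0.000 0.000 1.00 0.00 2 LYS A 1
ATOM 7 C C . LYS A 1 2 ? 5.809 1.420 0.000 1.00 0.00 2 LYS A 1
ATOM 8 O O . LYS A 1 2 ? 5.400 2.540 0.000 1.00 0.00 2 LYS A 1
ATOM 9 C CB . LYS A 1 2 ? 5.000 -1.100 0.800 1.00 0.00 2 LYS A 1
ATOM 10 C CG . LYS A 1 2 ? 5.600 -2.100 1.500 1.00 0.00 2 LYS A 1
ATOM 11 C CD . LYS A 1 2 ? 6.200 -3.100 2.100 1.00 0.00 2 LYS A 1
ATOM 12 C CE . LYS A 1 2 ? 6.800 -3.900 2.700 1.00 0.00 2 LYS A 1
ATOM 13 N NZ . LYS A 1 2 ? 7.200 -4.600 3.200 1.00 0.00 2 LYS A 1
ATOM 14 N N . ALA A 1 3 ? 7.600 0.000 0.000 1.00 0.00 3 ALA A 1
ATOM 15 C CA . ALA A 1 3 ? 9.058 0.000 0.000 1.00 0.00 3 ALA A 1
ATOM 16 C C . ALA A 1 3 ? 9.609 1.420 0.000 1.00 0.00 3 ALA A 1
ATOM 17 O O . ALA A 1 3 ? 9.200 2.540 0.000 1.00 0.00 3 ALA A 1
ATOM 18 N N . GLU A 1 4 ? 11.400 0.000 0.000 1.00 0.00 4 GLU A 1
ATOM 19 C CA . GLU A 1 4 ? 12.858 0.000 0.000 1.00 0.00 4 GLU A 1
ATOM 20 C C . GLU A 1 4 ? 13.409 1.420 0.000 1.00 0.00 4 GLU A 1
ATOM 21 O O . GLU A 1 4 ? 13.000 2.540 0.000 1.00 0.00 4 GLU A 1
#
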