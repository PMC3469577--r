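>sbi-MIR1432
UCAGGAAAGAUGACACCAA
>sbi-MIR156b
UUGACAGAAGAGAGUGAGCAC
>sbi-MIR160c
UGCCUGGCUCCCUGUAUGCCA
>sbi-MIR164b
UGGAGAAGCAGGGCACGUGCA
>sbi-MIR166a
UCGGACCAGGCUUCAUUCCCC
>sbi-MIR167c
UGAAGCUGCCAGCAUGAUCUGA
>sbi-MIR169f
CUAGCCAAGAAUGACUUGCCU
>sbi-MIR169a
CAGCCAAGGAUGACUUGCCGA
>sbi-MIR171h
UUGAGCCGCGUCAAUAUCUCC
>sbi-MIR171g
UGAUUGAGCCGUGCCAAUAUC
>sbi-MIR171c
UGAGCCGAACCAAUAUCACUC
>sbi-MIR172a
AGAAUCUUGAUGAUGCUGCAU
>sbi-MIR319b
UUUGGAUUGAAGGGUGCU
>sbi-MIR390
AAGCUCAGGAGGGAUAGCGCC
>sbi-MIR393b
CUCCAAAGGGAUCGCAUUGAU
>sbi-MIR394a
UUGGCAUUCUGUCCACCUCC
>sbi-MIR396d
UCCACAGGCUUUCUUGAACUG
>sbi-MIR397
UUGACUGCAGCGUUGAUGAGC
>sbi-MIR399a
UGCCAAAGGAGAGUUGCCCUG
>sbi-MIR528
UGGAAGGGGCAUGCAGAGGAG
>sbi-MIR529
AGAAGAGAGAGAGUACAGCCU
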