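source,target,sign,term,expert
C1,GC,1,very_low,E1
C1,GC,1,very_low,E2
C1,GC,1,very_low,E3
C2,GC,1,very_low,E1
C2,GC,1,very_low,E2
C2,GC,1,very_low,E3
C3,GC,1,very_low,E1
C3,GC,1,very_low,E2
C3,GC,1,low,E3
C4,GC,1,low,E1
C4,GC,1,low,E2
C4,GC,1,low,E3
C5,GC,-1,very_high,E1
C5,GC,-1,very_high,E2
C5,GC,-1,very_high,E3
C6,GC,1,low,E1
C6,GC,1,low,E2
C6,GC,1,low,E3
C7,GC,1,very_low,E1
C7,GC,1,very_low,E2
C7,GC,1,very_low,E3
C8,GC,1,low,E1
C8,GC,1,low,E2
C8,GC,1,low,E3
C9,GC,1,low,E1
C9,GC,1,low,E2
C9,GC,1,low,E3
C10,GC,-1,very_high,E1
C10,GC,-1,very_high,E2
C10,GC,-1,very_high,E3
C11,GC,1,very_low,E1
C11,GC,1,very_low,E2
C11,GC,1,low,E3
C12,GC,-1,very_high,E1
C12,GC,-1,very_high,E2
C12,GC,-1,very_high,E3
C13,GC,1,very_low,E1
C13,GC,1,very_low,E2
C13,GC,1,very_low,E3
C14,GC,1,very_low,E1
C14,GC,1,very_low,E2
C14,GC,1,very_low,E3
C15,GC,-1,very_high,E1
C15,GC,-1,very_high,E2
C15,GC,-1,very_high,E3
C16,GC,1,very_low,E1
C16,GC,1,very_low,E2
C16,GC,1,very_low,E3
C17,GC,1,very_low,E1
C17,GC,1,very_low,E2
C17,GC,1,very_low,E3
C18,GC,-1,high,E1
C18,GC,-1,high,E2
C18,GC,-1,very_high,E3
C19,GC,1,very_low,E1
C19,GC,1,very_low,E2
C19,GC,1,low,E3
C20,GC,1,low,E1
C20,GC,1,low,E2
C20,GC,1,medium,E3
C21,GC,-1,high,E1
C21,GC,-1,high,E2
C21,GC,-1,very_high,E3
C22,GC,1,very_low,E1
C22,GC,1,very_low,E2
C22,GC,1,very_low,E3
C23,GC,1,low,E1
C23,GC,1,low,E2
C23,GC,1,low,E3
C24,GC,1,very_low,E1
C24,GC,1,very_low,E2
C24,GC,1,very_low,E3
C25,GC,1,low,E1
C25,GC,1,low,E2
C25,GC,1,medium,E3
C26,GC,1,low,E1
C26,GC,1,low,E2
C26,GC,1,low,E3
C27,GC,1,low,E1
C27,GC,1,low,E2
C27,GC,1,low,E3
C8,C23,1,low,E1
C8,C23,1,low,E2
C8,C23,1,low,E3
C6,C23,1,low,E1
C6,C23,1,low,E2
C6,C23,1,very_low,E3
C3,C23,1,low,E1
C3,C23,1,very_low,E2
C3,C23,1,very_low,E3
C9,C26,1,medium,E1
C9,C26,1,medium,E2
C9,C26,1,low,E3
C25,C26,1,high,E1
C25,C26,1,high,E2
C25,C26,1,medium,E3
C24,C26,1,low,E1
C24,C26,1,low,E2
C24,C26,1,low,E3
C25,C27,1,high,E1
C25,C27,1,high,E2
C25,C27,1,high,E3
C23,C27,1,medium,E1
C23,C27,1,medium,E2
C23,C27,1,medium,E3
C26,C27,1,medium,E1
C26,C27,1,medium,E2
C26,C27,1,high,E3
C13,C3,1,low,E1
C13,C3,1,low,E2
C13,C3,1,low,E3
C5,C3,-1,medium,E1
C5,C3,-1,medium,E2
C5,C3,-1,medium,E3
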