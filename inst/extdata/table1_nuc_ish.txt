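nuc ish(5’MYCx3,3′MYCx2)(5’MYC con 3′MYCx2)[42/100]/(MYCx3)[30/100]
nuc ish(5′MYCx2,3′MYCx1)(5′MYC con 3′MYCx1)[100]
nuc ish,(5′MYCx2 ~ 3,3′MYCx1-2)(5′MYC con 3′MYCx1-2)[97/100]
nuc ish(5′MYCx2 ~ 3,3′MYCx1-2)(5′MYC con 3′MYCx1-2)[61/100]
nuc ish(5’MYCx2 ~ 5,3’MYCx1 ~ 2)(5’MYC con 3’MYCx1∼2)[100]
nuc ish(5’MYCx1 ~ 3,3’MYCx2 ~ 4)(5’MYC con 3’MYCx1∼3)[80/100]
nuc ish(5’MYCx1,3’MYCx2)(5’MYC con 3’MYCx1)[68/100]
nuc ish(5′MYCx2 ~ 4,3′MYCx2 ~ 4)(5′MYC sep 3′MYCx1)[90/100]
nuc ish(5′MYC,3′MYC)x2∼4(5′MYC con 3′MYCx1 ~ 2)[93/100]
nuc ish(5′MYCx2 ~ 5,3′MYCx2 ~ 5)(5′MYC con 3′MYCx1 ~ 2)[100]
nuc ish(MYCx2)(5′MYC sep 3′MYCx1)[96/100]
nuc ish(MYCx2)(5′MYC sep 3′MYCx1)[92/100]
nuc ish(MYCx2)(5′MYC sep 3′MYCx1)[94/100]
nuc ish(MYCx2)(5′MYC sep 3′MYCx1)[100]
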